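# Declarative analysis pipeline: one YAML/JSON config names the inputs
# (or a synthetic spec), the atom selections and the analysis blocks;
# every defaulted parameter is echoed back into the resolved config so a
# run is reproducible from its report alone.

ANALYSIS_DEFAULTS <- list(
  rmsd = list(selection = "protein", mass_weighted = TRUE),
  rmsf = list(selection = "protein", mass_weighted = TRUE,
              reference = "mean"),
  pca = list(selection = "protein", mass_weighted = TRUE),
  saltbridges = list(pairs = NULL, threshold = 0.6),
  density = list(waters = "waters", axis = NULL, lateral_radius = 2,
                 bin_width = 0.1),
  occupancy = list(selection = "waters", spacing = 0.1, isovalue = 0.2),
  crossings = list(waters = "waters", z_lower = NULL, z_upper = NULL,
                   lateral_radius = 2),
  permeability = list(region = NULL, bottom_resids = NULL,
                      top_resids = NULL, r = 2, waters = "waters",
                      n_subtraj = 100, subtraj_len = 50,
                      estimator = "mean_square", vw = 2.99e-23,
                      viscosity_scale = 2.87),
  contacts = list(groupA = NULL, groupB = NULL, cutoff = 0.35,
                  unique_atoms = FALSE)
)

TOP_KEYS <- c("seed", "output_dir", "input", "synthetic", "selections",
              "analyses", "resolved")
INPUT_KEYS <- c("structure", "trajectory", "format", "dt", "box")
SYN_KEYS <- c("kind", "seed", "n_frames", "dt", "box", "pore", "waters",
              "saltbridge", "binding")

#' Validate and resolve a pipeline configuration
#'
#' Fills defaults (pore radius 2 nm, contact cutoff 0.35 nm, viscosity
#' scale 2.87, 100 subtrajectories of 50 ps, salt-bridge threshold
#' 0.6 nm), rejects unknown keys, and checks that referenced files
#' exist. Validation is idempotent: a resolved config re-validates to
#' itself.
#'
#' @param config a named list, or a path to a YAML/JSON config file.
#' @return resolved config (class `poreflow_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  errors <- character(0)
  add_err <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))
  unknown <- setdiff(names(config), TOP_KEYS)
  if (length(unknown) > 0) {
    add_err("unknown top-level key(s): %s", paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$output_dir)) config$output_dir <- "poreflow_out"
  has_input <- !is.null(config$input)
  has_syn <- !is.null(config$synthetic)
  if (!has_input && !has_syn) add_err("config needs 'input' or 'synthetic'")
  if (has_input && has_syn) add_err("'input' and 'synthetic' are exclusive")
  if (has_input) {
    bad <- setdiff(names(config$input), INPUT_KEYS)
    if (length(bad) > 0) {
      add_err("unknown input key(s): %s", paste(bad, collapse = ", "))
    }
    for (f in c("structure", "trajectory")) {
      p <- config$input[[f]]
      if (!is.null(p) && !file.exists(p)) add_err("input %s not found: %s", f, p)
    }
    if (is.null(config$input$dt)) config$input$dt <- 1
  }
  if (has_syn) {
    bad <- setdiff(names(config$synthetic), SYN_KEYS)
    if (length(bad) > 0) {
      add_err("unknown synthetic key(s): %s", paste(bad, collapse = ", "))
    }
    if (is.null(config$synthetic$kind)) add_err("synthetic needs 'kind'")
  }
  if (is.null(config$selections)) config$selections <- list()
  if (is.null(config$selections$protein)) {
    config$selections$protein <- "not water"
  }
  if (is.null(config$selections$waters)) config$selections$waters <- "water"
  if (length(config$analyses) == 0) {
    add_err("config must request at least one analysis")
  }
  bad <- setdiff(names(config$analyses), names(ANALYSIS_DEFAULTS))
  if (length(bad) > 0) {
    add_err("unknown analysis block(s): %s (available: %s)",
            paste(bad, collapse = ", "),
            paste(names(ANALYSIS_DEFAULTS), collapse = ", "))
  }
  for (an in intersect(names(config$analyses), names(ANALYSIS_DEFAULTS))) {
    blk <- config$analyses[[an]]
    if (is.null(blk)) blk <- list()
    defs <- ANALYSIS_DEFAULTS[[an]]
    bad <- setdiff(names(blk), names(defs))
    if (length(bad) > 0) {
      add_err("analysis '%s': unknown key(s) %s", an,
              paste(bad, collapse = ", "))
    }
    for (k in names(defs)) if (is.null(blk[[k]])) blk[k] <- defs[k]
    config$analyses[[an]] <- blk
  }
  if (length(errors) > 0) {
    stop_pf("invalid config:\n  - %s", paste(errors, collapse = "\n  - "))
  }
  config$resolved <- TRUE
  class(config) <- "poreflow_config"
  config
}

resolve_selection <- function(spec, topology, selections) {
  if (is.null(spec)) stop_pf("missing selection")
  expr <- if (!is.null(selections[[spec]])) selections[[spec]] else spec
  select_atoms(topology, expr)
}

load_pipeline_trajectory <- function(config) {
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    if (is.null(syn$seed)) syn$seed <- derive_seed(config$seed, "synthetic")
    args <- syn[intersect(names(syn), c("kind", "seed", "n_frames", "dt",
                                        "box", "pore", "waters",
                                        "saltbridge", "binding"))]
    spec <- do.call(synthetic_spec, args)
    sys <- switch(spec$kind,
                  pore = make_pore_system(spec),
                  saltbridge = make_saltbridge_system(spec),
                  binding = make_binding_system(spec))
    return(sys)
  }
  inp <- config$input
  st <- read_structure(inp$structure, box = inp$box)
  traj <- if (!is.null(inp$trajectory)) {
    read_trajectory(inp$trajectory, st$topology, format = inp$format,
                    dt = inp$dt, box = inp$box)
  } else {
    trajectory(st$topology, array(st$frame$xyz, dim = c(nrow(st$topology), 3, 1)),
               st$frame$box, times = st$frame$time)
  }
  list(trajectory = traj, ground_truth = NULL, spec = NULL)
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes every configured analysis block against the loaded or
#' generated trajectory, writes per-stage CSV/JSON outputs plus a
#' machine-readable `report.json` (embedding the resolved config) under
#' the output directory, and returns the report. Stage failures are
#' recorded and do not prevent later independent stages from running.
#'
#' @param config a [validate_config()] result, raw list, or config path.
#' @return the run report (list), invisibly; attribute `ok` is FALSE if
#'   any stage failed.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "poreflow_config")) config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(config), stages = list())
  record <- function(name, status, outputs = NULL, summary = NULL,
                     error = NULL) {
    report$stages[[name]] <<- list(status = status, outputs = outputs,
                                   summary = summary, error = error)
  }
  sys <- tryCatch(load_pipeline_trajectory(config), error = function(e) e)
  if (inherits(sys, "error")) {
    record("io", "failed", error = conditionMessage(sys))
    report$ok <- FALSE
    jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    return(invisible(structure(report, ok = FALSE)))
  }
  traj <- sys$trajectory
  top <- traj$topology
  record("io", "ok", summary = list(n_atoms = nrow(top),
                                    n_frames = n_frames(traj)))
  sel_of <- function(spec) resolve_selection(spec, top, config$selections)
  out <- config$output_dir

  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      record(name, "failed", error = conditionMessage(res))
    } else {
      record(name, "ok", outputs = res$outputs, summary = res$summary)
    }
  }
  an <- config$analyses

  if (!is.null(an$rmsd)) run_stage("rmsd", function() {
    r <- rmsd_series(traj, sel_of(an$rmsd$selection),
                     mass_weighted = an$rmsd$mass_weighted)
    list(outputs = write_stage_csv(r, out, "rmsd.csv"),
         summary = list(mean_rmsd_nm = mean(r$rmsd_nm),
                        final_rmsd_nm = r$rmsd_nm[nrow(r)]))
  })
  if (!is.null(an$rmsf)) run_stage("rmsf", function() {
    r <- rmsf_profile(traj, sel_of(an$rmsf$selection),
                      mass_weighted = an$rmsf$mass_weighted,
                      reference = an$rmsf$reference)
    list(outputs = write_stage_csv(r, out, "rmsf.csv"),
         summary = list(mean_rmsf_nm = mean(r$rmsf_nm)))
  })
  if (!is.null(an$pca)) run_stage("pca", function() {
    r <- common_pca(list(traj), sel_of(an$pca$selection),
                    mass_weighted = an$pca$mass_weighted)
    p1 <- write_stage_csv(r$projections, out, "pca_projections.csv")
    p2 <- write_stage_csv(
      data.frame(component = seq_along(r$eigenvalues),
                 eigenvalue_nm2 = r$eigenvalues), out, "pca_eigenvalues.csv")
    list(outputs = c(p1, p2),
         summary = list(span_area_nm2 = pc_span_area(r$projections[, c("pc1", "pc2")]),
                        total_variance_nm2 = r$total_variance))
  })
  if (!is.null(an$saltbridges)) run_stage("saltbridges", function() {
    blk <- an$saltbridges
    if (is.null(blk$pairs)) stop_pf("saltbridges block needs 'pairs'")
    res <- saltbridge_network(traj, blk$pairs, threshold = blk$threshold)
    series <- do.call(rbind, lapply(res, function(r) {
      data.frame(pair = attr(r, "pair_label"), time_ps = r$time_ps,
                 distance_nm = r$distance_nm)
    }))
    occ <- data.frame(
      pair = vapply(res, attr, "", "pair_label"),
      occupancy = vapply(res, attr, 0, "occupancy"),
      threshold_nm = blk$threshold)
    list(outputs = c(write_stage_csv(series, out, "saltbridges.csv"),
                     write_stage_csv(occ, out, "occupancy.csv")),
         summary = list(occupancy = stats::setNames(occ$occupancy, occ$pair)))
  })
  if (!is.null(an$density)) run_stage("density", function() {
    blk <- an$density
    axis_sel <- if (!is.null(blk$axis)) sel_of(blk$axis) else NULL
    axis_center <- if (is.null(axis_sel)) traj$box[1, 1:2] / 2 else NULL
    prof <- z_density_profile(traj, sel_of(blk$waters), axis_sel = axis_sel,
                              axis_center = axis_center,
                              lateral_radius = blk$lateral_radius,
                              bin_width = blk$bin_width)
    list(outputs = write_stage_csv(prof, out, "density.csv"),
         summary = list(mean_count = attr(prof, "mean_count"),
                        min_density = min(prof$density_per_nm3)))
  })
  if (!is.null(an$occupancy)) run_stage("occupancy", function() {
    blk <- an$occupancy
    region <- list(min = c(0, 0, 0), max = traj$box[1, ])
    grid <- occupancy_grid(traj, sel_of(blk$selection), region,
                           spacing = blk$spacing)
    cont <- is_channel_continuous(grid, isovalue = blk$isovalue)
    path <- file.path(out, "occupancy.dx")
    write_opendx(grid, path)
    list(outputs = path,
         summary = list(continuous = cont$continuous,
                        n_components = cont$n_components))
  })
  if (!is.null(an$crossings)) run_stage("crossings", function() {
    blk <- an$crossings
    zl <- blk$z_lower
    zu <- blk$z_upper
    if (is.null(zl) || is.null(zu)) {
      if (!is.null(sys$spec) && sys$spec$kind == "pore") {
        ctr <- sys$spec$box[3] / 2
        zl <- ctr - sys$spec$pore$half_length
        zu <- ctr + sys$spec$pore$half_length
      } else {
        stop_pf("crossings block needs z_lower and z_upper")
      }
    }
    rep_ <- count_crossings(traj, sel_of(blk$waters), zl, zu,
                            lateral_radius = blk$lateral_radius)
    list(outputs = write_stage_csv(rep_$events, out, "crossings.csv"),
         summary = list(n_up = rep_$n_up, n_down = rep_$n_down))
  })
  if (!is.null(an$permeability)) run_stage("permeability", function() {
    blk <- an$permeability
    if (!is.null(blk$region)) {
      region <- define_pore_region(top, blk$region)
    } else if (!is.null(blk$bottom_resids)) {
      region <- define_pore_region(top, blk$bottom_resids, blk$top_resids,
                                   r = blk$r)
    } else if (!is.null(sys$spec) && sys$spec$kind == "pore") {
      nr <- sys$spec$pore$n_ring_atoms
      region <- define_pore_region(top, seq_len(nr), nr + seq_len(nr),
                                   r = blk$r)
    } else {
      stop_pf("permeability block needs a region or ring residue lists")
    }
    nt <- collective_displacement(traj, region, sel_of(blk$waters))
    fit <- fit_Dn(nt, n_subtraj = blk$n_subtraj,
                  subtraj_len = blk$subtraj_len, estimator = blk$estimator,
                  seed = derive_seed(config$seed, "bootstrap"))
    perm <- osmotic_permeability(fit, vw = blk$vw,
                                 viscosity_scale = blk$viscosity_scale)
    p1 <- write_stage_csv(nt, out, "n_of_t.csv")
    p2 <- write_stage_csv(fit$msd, out, "msd.csv")
    p3 <- file.path(out, "permeability.json")
    jsonlite::write_json(
      list(Dn_per_ps = perm$Dn, Dn_se = perm$Dn_se, vw_cm3 = perm$vw,
           viscosity_scale = perm$viscosity_scale, Pf_cm3_s = perm$Pf,
           Pf_se = perm$Pf_se, n_subtraj = blk$n_subtraj,
           subtraj_len_ps = blk$subtraj_len, estimator = blk$estimator,
           mean_occupancy = attr(nt, "mean_occupancy"),
           L_mean_nm = attr(nt, "L_mean")),
      p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(outputs = c(p1, p2, p3),
         summary = list(Dn_per_ps = perm$Dn, Pf_cm3_s = perm$Pf))
  })
  if (!is.null(an$contacts)) run_stage("contacts", function() {
    blk <- an$contacts
    if (is.null(blk$groupA) || is.null(blk$groupB)) {
      stop_pf("contacts block needs groupA and groupB")
    }
    cs <- contact_count_series(traj, sel_of(blk$groupA), sel_of(blk$groupB),
                               cutoff = blk$cutoff,
                               unique_atoms = blk$unique_atoms)
    df <- data.frame(time_ps = cs$time_ps, count = cs$count,
                     cutoff_nm = blk$cutoff,
                     groups = paste(blk$groupA, blk$groupB, sep = "|"))
    list(outputs = write_stage_csv(df, out, "contacts.csv"),
         summary = list(mean_contacts = mean(cs$count)))
  })

  statuses <- vapply(report$stages, function(s) s$status, "")
  report$ok <- all(statuses == "ok")
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(structure(report, ok = report$ok))
}
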