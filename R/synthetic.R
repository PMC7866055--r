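#' Specify a synthetic test system
#'
#' Parameterizes a generated trajectory with analytically known ground
#' truth. Three kinds are available:
#' \describe{
#'   \item{pore}{Independent Brownian waters (single pseudo-atoms,
#'     per-axis increment variance `2*D*dt`) around a membrane slab
#'     pierced by a cylindrical channel. The slab faces reflect; inside
#'     the channel the radial wall reflects; `barrier = TRUE` adds a
#'     reflecting mid-plane so no molecule can traverse. Two static rings
#'     of pseudo C-alpha atoms at the channel mouths define the pore
#'     region for downstream analyses.}
#'   \item{saltbridge}{Two 3-atom pseudo-residues whose centre-of-mass
#'     separation follows a two-state telegraph process (rates `k_on`,
#'     `k_off` per ps) between `bound_mean` and `unbound_mean`, plus
#'     Gaussian noise. Stationary bound fraction `k_on/(k_on+k_off)` is
#'     the exact occupancy oracle.}
#'   \item{binding}{A static 3-atom binding-site residue plus an
#'     `n_beads` ligand chain tethered with its head bead at
#'     `tether_distance` from the site, jittered per frame; the contact
#'     ground truth is an exhaustive pairwise recount at 0.35 nm on the
#'     generated coordinates.}
#' }
#'
#' Defaults describe the reference conditions used throughout the test
#' suite: pore systems mirror the permeability protocol (frames saved
#' every 0.5 ps, 5 ns span, channel length 2 nm, TIP3P-like
#' D = 2.3e-3 nm^2/ps, water count chosen for a mean channel occupancy
#' near 10).
#'
#' @param kind `"pore"`, `"saltbridge"` or `"binding"`.
#' @param seed integer RNG seed; identical spec + seed reproduce the
#'   trajectory exactly.
#' @param n_frames,dt,box trajectory length, frame spacing (ps) and box
#'   edge lengths (nm).
#' @param pore,waters,saltbridge,binding named lists overriding the
#'   kind-specific defaults (see Details).
#' @return object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(kind = c("pore", "saltbridge", "binding"),
                           seed = 1, n_frames = NULL, dt = NULL, box = NULL,
                           pore = list(), waters = list(),
                           saltbridge = list(), binding = list()) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    pore = list(
      n_frames = 10001, dt = 0.5, box = c(2.5, 2.5, 5),
      pore = list(ring_radius = 0.6, half_length = 1.0, n_ring_atoms = 6,
                  channel_radius = 0.6, barrier = FALSE),
      waters = list(count = 93, D = 2.3e-3)),
    saltbridge = list(
      n_frames = 10000, dt = 1, box = c(5, 5, 5),
      saltbridge = list(bound_mean = 0.45, unbound_mean = 0.95,
                        noise_sd = 0.05, k_on = 0.02, k_off = 0.02)),
    binding = list(
      n_frames = 500, dt = 1, box = c(6, 6, 6),
      binding = list(n_beads = 20, tether_distance = 0.3, jitter_sd = 0.02,
                     bead_spacing = 0.15, site_atoms = 3))
  )
  merge1 <- function(base, user) {
    unknown <- setdiff(names(user), names(base))
    if (length(unknown) > 0) {
      stop_pf("unknown %s parameter(s): %s", kind,
              paste(unknown, collapse = ", "))
    }
    base[names(user)] <- user
    base
  }
  spec <- list(
    kind = kind, seed = as.integer(seed),
    n_frames = if (is.null(n_frames)) defaults$n_frames else as.integer(n_frames),
    dt = if (is.null(dt)) defaults$dt else dt,
    box = if (is.null(box)) defaults$box else as.numeric(box))
  if (kind == "pore") {
    spec$pore <- merge1(defaults$pore, pore)
    spec$waters <- merge1(defaults$waters, waters)
    if (spec$waters$count < 1) stop_pf("waters$count must be >= 1")
    if (spec$waters$D <= 0) stop_pf("waters$D must be > 0")
    if (spec$pore$channel_radius >= min(spec$box[1:2]) / 2) {
      stop_pf("channel_radius must be < min(box x, box y)/2")
    }
    if (2 * spec$pore$half_length >= spec$box[3]) {
      stop_pf("slab (2*half_length) must fit inside the box z edge")
    }
  } else if (kind == "saltbridge") {
    spec$saltbridge <- merge1(defaults$saltbridge, saltbridge)
    sb <- spec$saltbridge
    if (!(sb$bound_mean > 0 && sb$bound_mean < sb$unbound_mean)) {
      stop_pf("need 0 < bound_mean < unbound_mean")
    }
    if (sb$noise_sd >= (sb$unbound_mean - sb$bound_mean) / 2) {
      stop_pf("noise_sd too large: bound/unbound states not separable")
    }
    if (sb$k_on < 0 || sb$k_off < 0 || sb$k_on + sb$k_off == 0) {
      stop_pf("rates must be non-negative with k_on + k_off > 0")
    }
  } else {
    spec$binding <- merge1(defaults$binding, binding)
    if (spec$binding$n_beads < 1) stop_pf("n_beads must be >= 1")
  }
  if (spec$dt <= 0) stop_pf("dt must be > 0")
  if (spec$n_frames < 2) stop_pf("n_frames must be >= 2")
  class(spec) <- "SyntheticSpec"
  spec
}

#' Generate an open or blocked cylindrical-pore water system
#'
#' Propagates independent Brownian pseudo-waters around a reflecting
#' membrane slab pierced by a cylindrical channel (see
#' [synthetic_spec()]). For the open channel the collective-diffusion
#' ground truth is `expected_Dn = N_in * D / L^2`, with `N_in` the
#' time-averaged channel occupancy measured on the generated trajectory
#' and `L = 2 * half_length`; the expected two-way crossing rate is
#' `2 * N_in * D / L^2` (tracer-flux identity for independent
#' diffusers).
#'
#' @param spec a [synthetic_spec()] with `kind = "pore"`.
#' @return list with `trajectory`, `ground_truth` (class `GroundTruth`)
#'   and `spec`.
#' @export
make_pore_system <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (spec$kind != "pore") stop_pf("spec kind must be 'pore'")
  set.seed(spec$seed, kind = "Mersenne-Twister")
  p <- spec$pore
  nw <- spec$waters$count
  D <- spec$waters$D
  box <- spec$box
  ctr <- box / 2
  h <- p$half_length
  Rc <- p$channel_radius
  nf <- spec$n_frames
  sd_step <- sqrt(2 * D * spec$dt)

  # ring scaffold: bottom ring at z = ctr - h, top at ctr + h
  nr <- p$n_ring_atoms
  ang <- 2 * pi * (seq_len(nr) - 1) / nr
  ring_xy <- cbind(ctr[1] + p$ring_radius * cos(ang),
                   ctr[2] + p$ring_radius * sin(ang))
  ring_xyz <- rbind(cbind(ring_xy, ctr[3] - h), cbind(ring_xy, ctr[3] + h))
  top <- topology(
    atom_name = c(rep("CA", 2 * nr), rep("OW", nw)),
    resname = c(rep("RNG", 2 * nr), rep("SOL", nw)),
    resid = c(seq_len(2 * nr), 2 * nr + seq_len(nw)),
    mass = c(rep(12.011, 2 * nr), rep(18.015, nw)))

  # initial positions: uniform over the accessible volume (stationary)
  v_ch <- pi * Rc^2 * 2 * h
  v_bulk <- box[1] * box[2] * (box[3] - 2 * h)
  n_ch0 <- stats::rbinom(1, nw, v_ch / (v_ch + v_bulk))
  pos <- matrix(0, nw, 3)
  if (n_ch0 > 0) {
    rr <- Rc * sqrt(stats::runif(n_ch0))
    th <- stats::runif(n_ch0, 0, 2 * pi)
    pos[seq_len(n_ch0), ] <- cbind(ctr[1] + rr * cos(th),
                                   ctr[2] + rr * sin(th),
                                   stats::runif(n_ch0, ctr[3] - h, ctr[3] + h))
  }
  if (n_ch0 < nw) {
    nb <- nw - n_ch0
    zb <- stats::runif(nb, 0, box[3] - 2 * h)
    zb <- ifelse(zb < ctr[3] - h, zb, zb + 2 * h)
    pos[n_ch0 + seq_len(nb), ] <- cbind(stats::runif(nb, 0, box[1]),
                                        stats::runif(nb, 0, box[2]), zb)
  }

  xyz <- array(0, dim = c(2 * nr + nw, 3, nf))
  occupancy <- numeric(nf)
  widx <- 2 * nr + seq_len(nw)
  in_slab <- function(z) abs(z - ctr[3]) <= h
  for (i in seq_len(nf)) {
    if (i > 1) {
      old <- pos
      pos <- pos + matrix(stats::rnorm(nw * 3, sd = sd_step), nw, 3)
      pos <- wrap_box(pos, box)
      newslab <- in_slab(pos[, 3])
      oldslab <- in_slab(old[, 3])
      r2new <- (pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2
      # bulk -> slab outside the channel: reflect off the membrane face
      hit_face <- newslab & !oldslab & r2new > Rc^2
      if (any(hit_face)) {
        face <- ifelse(old[hit_face, 3] > ctr[3], ctr[3] + h, ctr[3] - h)
        pos[hit_face, 3] <- 2 * face - pos[hit_face, 3]
      }
      # channel -> radial wall: reflect at the cylinder surface
      hit_wall <- newslab & oldslab & r2new > Rc^2
      if (any(hit_wall)) {
        rn <- sqrt(r2new[hit_wall])
        scl <- (2 * Rc - rn) / rn
        pos[hit_wall, 1] <- ctr[1] + (pos[hit_wall, 1] - ctr[1]) * scl
        pos[hit_wall, 2] <- ctr[2] + (pos[hit_wall, 2] - ctr[2]) * scl
      }
      if (isTRUE(p$barrier)) {
        # reflecting mid-plane: no in-channel sign change of z - ctr[3]
        newslab <- in_slab(pos[, 3])
        crossed <- newslab & (sign(pos[, 3] - ctr[3]) !=
                              sign(old[, 3] - ctr[3])) &
                   sign(old[, 3] - ctr[3]) != 0
        if (any(crossed)) pos[crossed, 3] <- 2 * ctr[3] - pos[crossed, 3]
      }
    }
    r2 <- (pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2
    occupancy[i] <- sum(in_slab(pos[, 3]) & r2 <= Rc^2)
    xyz[widx, , i] <- pos
    xyz[seq_len(2 * nr), , i] <- ring_xyz
  }
  traj <- trajectory(top, xyz, box, dt = spec$dt)
  L <- 2 * h
  n_in <- mean(occupancy)
  gt <- structure(list(
    kind = "pore",
    expected_Dn = if (p$barrier) 0 else n_in * D / L^2,
    mean_occupancy = n_in,
    expected_crossing_rate = if (p$barrier) 0 else 2 * n_in * D / L^2 * 1000,
    L = L), class = "GroundTruth")
  list(trajectory = traj, ground_truth = gt, spec = spec)
}

#' Generate a two-state salt-bridge distance system
#'
#' @param spec a [synthetic_spec()] with `kind = "saltbridge"`.
#' @return list with `trajectory`, `ground_truth` (holding
#'   `expected_occupancy = k_on/(k_on+k_off)` and the realized state
#'   series) and `spec`.
#' @export
make_saltbridge_system <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (spec$kind != "saltbridge") stop_pf("spec kind must be 'saltbridge'")
  set.seed(spec$seed, kind = "Mersenne-Twister")
  sb <- spec$saltbridge
  nf <- spec$n_frames
  p_bound <- sb$k_on / (sb$k_on + sb$k_off)
  p_on <- 1 - exp(-sb$k_on * spec$dt)   # unbound -> bound per step
  p_off <- 1 - exp(-sb$k_off * spec$dt) # bound -> unbound per step
  state <- logical(nf)                  # TRUE = bound
  state[1] <- stats::runif(1) < p_bound
  u <- stats::runif(nf)
  for (i in 2:nf) {
    state[i] <- if (state[i - 1]) u[i] >= p_off else u[i] < p_on
  }
  dist <- ifelse(state, sb$bound_mean, sb$unbound_mean) +
    stats::rnorm(nf, sd = sb$noise_sd)
  dist <- pmax(dist, 0.05)

  # residue A fixed at the box centre; residue B displaced along x so the
  # centre-of-mass separation equals the telegraph distance exactly
  masses <- c(12.011, 12.011, 15.999)
  geomA <- rbind(c(0, 0, 0), c(0.12, 0, 0), c(0.06, 0.1, 0))
  geomA <- sweep(geomA, 2, com(geomA, masses))   # COM at origin
  ctr <- spec$box / 2
  top <- topology(atom_name = rep(c("CB", "CG", "OD1"), 2),
                  resname = c(rep("ASP", 3), rep("LYS", 3)),
                  resid = c(rep(1L, 3), rep(2L, 3)),
                  mass = rep(masses, 2))
  xyz <- array(0, dim = c(6, 3, nf))
  A <- sweep(geomA, 2, ctr, "+")
  for (i in seq_len(nf)) {
    xyz[1:3, , i] <- A
    xyz[4:6, , i] <- sweep(geomA, 2, ctr + c(dist[i], 0, 0), "+")
  }
  traj <- trajectory(top, xyz, spec$box, dt = spec$dt)
  gt <- structure(list(kind = "saltbridge",
                       expected_occupancy = p_bound,
                       states = state, distances = dist),
                  class = "GroundTruth")
  list(trajectory = traj, ground_truth = gt, spec = spec)
}

#' Generate a ligand bead-chain binding system
#'
#' @param spec a [synthetic_spec()] with `kind = "binding"`.
#' @return list with `trajectory`, `ground_truth` (per-frame exhaustive
#'   contact counts at 0.35 nm between site and ligand atoms) and `spec`.
#' @export
make_binding_system <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (spec$kind != "binding") stop_pf("spec kind must be 'binding'")
  set.seed(spec$seed, kind = "Mersenne-Twister")
  b <- spec$binding
  nf <- spec$n_frames
  ctr <- spec$box / 2
  ns <- if (is.null(b$site_atoms)) 3L else as.integer(b$site_atoms)
  if (!ns %in% c(1L, 3L)) stop_pf("site_atoms must be 1 or 3")
  site_geom <- rbind(c(0, 0, 0), c(0.1, 0.08, 0), c(0.1, -0.08, 0))[seq_len(ns), ,
                                                                    drop = FALSE]
  site_mass <- c(12.011, 14.007, 14.007)[seq_len(ns)]
  site_geom <- sweep(site_geom, 2, com(site_geom, site_mass))
  site <- sweep(site_geom, 2, ctr, "+")
  nb <- b$n_beads
  chain0 <- cbind(b$tether_distance + b$bead_spacing * (seq_len(nb) - 1), 0, 0)
  top <- topology(atom_name = c(c("CZ", "NH1", "NH2")[seq_len(ns)],
                                paste0("C", seq_len(nb))),
                  resname = c(rep("ARG", ns), rep("AA", nb)),
                  resid = c(rep(60L, ns), rep(500L, nb)),
                  mass = c(site_mass, rep(12.011, nb)))
  xyz <- array(0, dim = c(ns + nb, 3, nf))
  counts <- integer(nf)
  cutoff <- 0.35
  for (i in seq_len(nf)) {
    jit <- matrix(stats::rnorm(nb * 3, sd = b$jitter_sd), nb, 3)
    chain <- sweep(chain0 + jit, 2, ctr, "+")
    xyz[seq_len(ns), , i] <- site
    xyz[ns + seq_len(nb), , i] <- chain
    d <- min_image(chain[rep(seq_len(nb), each = ns), , drop = FALSE] -
                   site[rep(seq_len(ns), nb), , drop = FALSE], spec$box)
    counts[i] <- sum(sqrt(rowSums(d^2)) < cutoff)
  }
  traj <- trajectory(top, xyz, spec$box, dt = spec$dt)
  gt <- structure(list(kind = "binding", expected_contacts = counts,
                       cutoff = cutoff, site_resid = 60L),
                  class = "GroundTruth")
  list(trajectory = traj, ground_truth = gt, spec = spec)
}

#' Write a synthetic system to disk
#'
#' Writes the trajectory as multi-frame GRO plus a JSON sidecar holding
#' the generating spec and its analytic ground truth.
#'
#' @param system result of a `make_*_system()` generator.
#' @param dir output directory (created if needed).
#' @param name basename for the two files.
#' @return invisibly, the paths written.
#' @export
write_system <- function(system, dir, name = system$spec$kind) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj_path <- file.path(dir, paste0(name, ".gro"))
  meta_path <- file.path(dir, paste0(name, ".json"))
  write_trajectory(system$trajectory, traj_path)
  meta <- list(spec = unclass(system$spec),
               ground_truth = unclass(system$ground_truth))
  meta$ground_truth$states <- NULL  # keep sidecar compact
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(trajectory = traj_path, metadata = meta_path))
}
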