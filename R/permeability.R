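# Collective-diffusion estimate of single-channel osmotic water
# permeability. The pore is the cylinder between the centres of mass of
# two C-alpha rings; net water motion through it is tracked as a
# dimensionless collective coordinate n(t) (axial displacements in units
# of pore lengths, clipped at the region boundaries), whose diffusion
# coefficient D_n gives P_f = v_w * D_n after viscosity rescaling.

#' Pore-region presets
#'
#' Ring residue lists delineating the central pore of the two UCP2
#' models, in author numbering: the NMR-based model uses two rings of
#' six C-alpha atoms, the homology model rings of five. Radius defaults
#' to 2 nm for both.
#'
#' @return named list with `bottom_resids`, `top_resids`, `r` per preset.
#' @export
pore_region_configs <- function() {
  list(
    ucp2_nmr = list(bottom_resids = c(34L, 85L, 137L, 181L, 239L, 274L),
                    top_resids = c(20L, 101L, 120L, 194L, 227L, 288L),
                    r = 2),
    ucp2_h = list(bottom_resids = c(34L, 82L, 137L, 181L, 274L),
                  top_resids = c(20L, 101L, 120L, 192L, 288L),
                  r = 2)
  )
}

#' Define a cylindrical pore region from two C-alpha rings
#'
#' Each listed residue must contain exactly one C-alpha atom; the
#' per-frame cylinder runs between the mass-weighted centres of the
#' bottom and top ring with radius `r`.
#'
#' @param topology a [topology()].
#' @param bottom_resids,top_resids author residue ids of the two rings,
#'   or a preset name from [pore_region_configs()] in `bottom_resids`.
#' @param r cylinder radius (nm); chosen large enough to enclose all
#'   pore waters.
#' @param ca_name atom name of the ring atoms.
#' @return object of class `PoreRegion`.
#' @export
define_pore_region <- function(topology, bottom_resids, top_resids = NULL,
                               r = 2, ca_name = "CA") {
  if (is.character(bottom_resids) && length(bottom_resids) == 1) {
    cfg <- pore_region_configs()
    if (!bottom_resids %in% names(cfg)) {
      stop_pf("unknown pore-region preset '%s'", bottom_resids)
    }
    preset <- cfg[[bottom_resids]]
    top_resids <- preset$top_resids
    r <- preset$r
    bottom_resids <- preset$bottom_resids
  }
  pick_ring <- function(resids, ring) {
    idx <- vapply(resids, function(rid) {
      hits <- which(topology$resid == rid & topology$atom_name == ca_name)
      if (length(hits) == 0) {
        stop_pf("%s ring: residue %d has no %s atom", ring, rid, ca_name)
      }
      if (length(hits) > 1) {
        stop_pf("%s ring: residue %d has %d %s atoms", ring, rid,
                length(hits), ca_name)
      }
      hits
    }, integer(1))
    as_selection(idx, sprintf("%s ring (%s)", ring,
                              paste(resids, collapse = ",")))
  }
  structure(list(bottom_ring = pick_ring(bottom_resids, "bottom"),
                 top_ring = pick_ring(top_resids, "top"),
                 r = r), class = "PoreRegion")
}

#' Per-frame pore-region geometry
#'
#' @param region a [define_pore_region()] object.
#' @param traj a [trajectory()].
#' @return list of per-frame matrices/vectors: `R0`, `R1` (ring COMs,
#'   nm), `e` (unit axis), `L` (length, nm).
#' @export
pore_region_geometry <- function(region, traj) {
  R0 <- com_series(traj, region$bottom_ring)
  R1 <- com_series(traj, region$top_ring)
  axis <- R1 - R0
  L <- sqrt(rowSums(axis^2))
  if (any(L <= 0)) stop_pf("degenerate pore region: zero-length axis")
  list(R0 = R0, R1 = R1, e = axis / L, L = L)
}

#' Collective water displacement through the pore
#'
#' Accumulates the collective coordinate
#' `n(t+dt) = n(t) + sum_i dr_i . e / L` over the molecules found inside
#' the cylinder at either end of each frame pair. Inter-frame
#' displacements are minimum-image unwrapped; the axial displacement of
#' molecules that enter or exit between frames is clipped to the part of
#' the straight-line path whose axial coordinate lies in `[0, L]`, so
#' only motion inside the region is counted. Radial excursions within a
#' step are not clipped.
#'
#' @param traj a [trajectory()] with >= 2 frames.
#' @param region a [define_pore_region()] object.
#' @param waters selection with one tracking point per water molecule.
#' @return object of class `CollectiveDisplacementSeries`: data.frame
#'   with `time_ps` and `n` (n(0) = 0), with attributes `dt`,
#'   `mean_occupancy`, `L_mean`.
#' @export
collective_displacement <- function(traj, region, waters) {
  nf <- n_frames(traj)
  if (nf < 2) stop_pf("need >= 2 frames")
  geom <- pore_region_geometry(region, traj)
  nw <- length(waters)
  byframe <- function(v) matrix(v, nw, nf, byrow = TRUE)
  # axial coordinate A and squared radial distance per frame, own-frame
  # geometry; vectorized over (molecule, frame)
  A <- matrix(0, nw, nf)
  RAD2 <- matrix(0, nw, nf)
  DA <- matrix(0, nw, nf - 1)    # axial displacement, frame-t geometry
  for (k in 1:3) {
    Wk <- matrix(traj$xyz[waters, k, ], nw, nf)
    relk <- Wk - byframe(geom$R0[, k])
    A <- A + relk * byframe(geom$e[, k])
    RAD2 <- RAD2 + relk^2
    Dk <- Wk[, -1, drop = FALSE] - Wk[, -nf, drop = FALSE]
    bk <- matrix(traj$box[-nf, k], nw, nf - 1, byrow = TRUE)
    Dk <- Dk - bk * round(Dk / bk)
    if (any(abs(Dk) > bk / 2 + 1e-9)) {
      stop_pf("sampling too sparse: displacement exceeds half the box")
    }
    DA <- DA + Dk * matrix(geom$e[-nf, k], nw, nf - 1, byrow = TRUE)
  }
  RAD2 <- RAD2 - A^2
  Lmat <- byframe(geom$L)
  inside <- A >= 0 & A <= Lmat & RAD2 <= region$r^2
  member <- inside[, -nf, drop = FALSE] | inside[, -1, drop = FALSE]
  A0 <- A[, -nf, drop = FALSE]
  A1 <- A0 + DA
  L0 <- Lmat[, -nf, drop = FALSE]
  contrib <- (pmin(pmax(A1, 0), L0) - pmin(pmax(A0, 0), L0)) / L0
  contrib[!member] <- 0
  dn <- colSums(contrib)
  occ <- colSums(inside)
  out <- data.frame(time_ps = traj$times, n = c(0, cumsum(dn)))
  attr(out, "dt") <- traj$dt
  attr(out, "mean_occupancy") <- mean(occ)
  attr(out, "L_mean") <- mean(geom$L)
  class(out) <- c("CollectiveDisplacementSeries", "data.frame")
  out
}

#' Fit the collective diffusion coefficient D_n
#'
#' Cuts the n(t) series into `n_subtraj` disjoint consecutive blocks of
#' `subtraj_len` ps, re-zeroes each block, averages the squared
#' displacement over blocks, and fits `MSD(tau) = 2 * D_n * tau` through
#' the origin over `tau` in (0, subtraj_len]. The default protocol (100
#' blocks of 50 ps) tiles a 5 ns analysis window exactly. The standard
#' error is obtained by bootstrap resampling of blocks.
#'
#' @param series a [collective_displacement()] result.
#' @param n_subtraj number of subtrajectory blocks.
#' @param subtraj_len block length in ps.
#' @param estimator `"mean_square"` fits the mean of `n(tau)^2` over
#'   blocks (the collective-diffusion definition, default);
#'   `"square_mean"` fits the square of the block-mean displacement.
#' @param n_boot bootstrap resamples for the SE.
#' @param seed RNG seed for the bootstrap.
#' @return list with `Dn` (1/ps), `se`, `msd` (data.frame `tau_ps`,
#'   `msd`), `n_subtraj`, `subtraj_len`.
#' @export
fit_Dn <- function(series, n_subtraj = 100, subtraj_len = 50,
                   estimator = c("mean_square", "square_mean"),
                   n_boot = 200, seed = 1) {
  estimator <- match.arg(estimator)
  dt <- attr(series, "dt")
  fpb <- as.integer(round(subtraj_len / dt))
  if (fpb < 1) stop_pf("subtraj_len shorter than one frame spacing")
  need <- n_subtraj * fpb + 1
  if (nrow(series) < need) {
    stop_pf("series too short: need %d frames for %d x %g ps at dt %g, have %d",
            need, n_subtraj, subtraj_len, dt, nrow(series))
  }
  # block b covers frames [(b-1)*fpb + 1, b*fpb + 1]; re-zeroed at start
  starts <- (seq_len(n_subtraj) - 1) * fpb + 1
  blocks <- vapply(starts, function(s) {
    series$n[s + seq_len(fpb)] - series$n[s]
  }, numeric(fpb))                      # fpb x n_subtraj
  tau <- seq_len(fpb) * dt
  msd_of <- function(B) {
    if (estimator == "mean_square") rowMeans(B^2) else rowMeans(B)^2
  }
  slope_of <- function(msd) sum(msd * tau) / sum(tau^2)
  msd <- msd_of(blocks)
  Dn <- slope_of(msd) / 2
  set.seed(seed, kind = "Mersenne-Twister")
  boot <- vapply(seq_len(n_boot), function(b) {
    pick <- sample.int(n_subtraj, replace = TRUE)
    slope_of(msd_of(blocks[, pick, drop = FALSE])) / 2
  }, numeric(1))
  list(Dn = Dn, se = stats::sd(boot),
       msd = data.frame(tau_ps = tau, msd = msd),
       n_subtraj = n_subtraj, subtraj_len = subtraj_len,
       estimator = estimator)
}

#' Osmotic permeability from the collective diffusion coefficient
#'
#' `P_f = v_w * D_n / viscosity_scale`, with `D_n` converted from 1/ps
#' to 1/s. The default `v_w` is the average volume of one water molecule
#' at 0.997 g/cm^3 (18.015 g/mol / (0.997 g/cm^3 x N_A) = 2.99e-23
#' cm^3). The default viscosity divisor 2.87 corrects for the low shear
#' viscosity of TIP3P-like water models relative to real water; set it
#' to 1 to disable.
#'
#' @param Dn collective diffusion coefficient (1/ps), or a [fit_Dn()]
#'   result (from which `se` is also taken).
#' @param se standard error of `Dn` (1/ps).
#' @param vw average single-water volume (cm^3).
#' @param viscosity_scale dimensionless divisor applied to `P_f`.
#' @return object of class `PermeabilityResult`: list with `Dn`, `Dn_se`
#'   (1/ps), `vw`, `viscosity_scale`, `Pf`, `Pf_se` (cm^3/s).
#' @export
osmotic_permeability <- function(Dn, se = 0, vw = 2.99e-23,
                                 viscosity_scale = 2.87) {
  fit <- NULL
  if (is.list(Dn)) {
    fit <- Dn
    se <- fit$se
    Dn <- fit$Dn
  }
  if (!is.finite(Dn) || Dn < 0) {
    stop_pf("Dn must be a non-negative number (got %s); inspect the MSD fit",
            format(Dn))
  }
  conv <- 1e12  # 1/ps -> 1/s
  structure(list(Dn = Dn, Dn_se = se, vw = vw,
                 viscosity_scale = viscosity_scale,
                 Pf = vw * Dn * conv / viscosity_scale,
                 Pf_se = vw * se * conv / viscosity_scale,
                 fit = fit), class = "PermeabilityResult")
}

#' @export
print.PermeabilityResult <- function(x, ...) {
  cat(sprintf("Osmotic permeability: Pf = %.3g +/- %.2g cm^3/s\n",
              x$Pf, x$Pf_se))
  cat(sprintf("  Dn = %.3g +/- %.2g ps^-1, vw = %.3g cm^3, viscosity scale %g\n",
              x$Dn, x$Dn_se, x$vw, x$viscosity_scale))
  invisible(x)
}
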