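#' Weighted rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the weighted RMSD
#' between two coordinate sets. Reflections are corrected, so the
#' returned rotation always has determinant +1.
#'
#' @param mobile,reference n x 3 coordinate matrices (nm), n >= 3.
#' @param weights per-atom weights (typically masses); unit weights if
#'   `NULL`.
#' @return object of class `SuperpositionResult`: list with `rotation`
#'   (3 x 3), `translation` (length 3), `rmsd_after` (nm) and `aligned`
#'   (the transformed mobile coordinates). The transform is
#'   `aligned = mobile %*% t(rotation) + translation`.
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3) {
    stop_pf("mobile and reference must be matching n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) stop_pf("superposition needs at least 3 atoms")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  M <- sweep(mobile, 2, cm)
  R <- sweep(reference, 2, cr)
  # collinearity check on the reference
  sv_ref <- svd(R * sqrt(w))$d
  if (sv_ref[2] < 1e-10 * max(sv_ref[1], 1e-300)) {
    stop_pf("degenerate geometry: reference atoms are collinear")
  }
  H <- t(M * w) %*% R
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- M %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((aligned - R)^2)))
  aligned <- sweep(aligned, 2, cr, "+")
  structure(list(rotation = rot, translation = as.numeric(cr - rot %*% cm),
                 rmsd_after = rmsd, aligned = aligned),
            class = "SuperpositionResult")
}

weights_for <- function(topology, sel, mass_weighted = TRUE) {
  if (mass_weighted) topology$mass[sel] else rep(1, length(sel))
}

#' RMSD time series
#'
#' Per-frame mass-weighted RMSD over a selection, after superposing each
#' frame onto the reference over the same selection. The reference
#' defaults to the first trajectory frame.
#'
#' @param traj a [trajectory()].
#' @param sel a [select_atoms()] selection (non-empty).
#' @param reference reference [frame()]; first frame if `NULL`.
#' @param mass_weighted use masses as superposition/RMSD weights.
#' @return object of class `RmsdSeries`: data.frame with `time_ps`,
#'   `rmsd_nm`.
#' @export
rmsd_series <- function(traj, sel, reference = NULL, mass_weighted = TRUE) {
  if (length(sel) == 0) stop_pf("empty selection")
  ref <- if (is.null(reference)) get_frame(traj, 1) else reference
  refx <- ref$xyz[sel, , drop = FALSE]
  w <- weights_for(traj$topology, sel, mass_weighted)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    superpose(coords_at(traj, sel, i), refx, w)$rmsd_after
  }, numeric(1))
  structure(data.frame(time_ps = traj$times, rmsd_nm = vals),
            class = c("RmsdSeries", "data.frame"))
}

# Iterated-mean superposition: superpose all frames onto the running mean
# structure until the mean stops moving. Returns the stack of aligned
# coordinate sets and the converged mean.
align_to_mean <- function(coord_list, weights, tol = 1e-6, max_iter = 100) {
  mean_x <- coord_list[[1]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(coord_list, function(x) {
      superpose(x, mean_x, weights)$aligned
    })
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    shift <- sqrt(max(rowSums((new_mean - mean_x)^2)))
    mean_x <- new_mean
    if (shift < tol) break
  }
  list(aligned = aligned, mean = mean_x)
}

#' RMSF per residue
#'
#' Root mean square fluctuation of each selected atom about the iterated
#' mean structure (all frames are superposed onto the time-average
#' structure, which is re-derived until converged), reported per residue
#' in author numbering. With `reference = "first"` frames are superposed
#' onto frame 1 instead.
#'
#' @param traj a [trajectory()] with >= 2 frames.
#' @param sel selection (one atom per residue for the usual C-alpha use).
#' @param mass_weighted use masses as superposition weights.
#' @param reference `"mean"` (default) or `"first"`.
#' @return object of class `RmsfProfile`: data.frame with `resid`,
#'   `rmsf_nm`, one row per selected residue.
#' @export
rmsf_profile <- function(traj, sel, mass_weighted = TRUE,
                         reference = c("mean", "first")) {
  reference <- match.arg(reference)
  if (length(sel) == 0) stop_pf("empty selection")
  if (n_frames(traj) < 2) stop_pf("RMSF undefined for a single frame")
  w <- weights_for(traj$topology, sel, mass_weighted)
  coords <- lapply(seq_len(n_frames(traj)), function(i) {
    coords_at(traj, sel, i)
  })
  if (reference == "mean") {
    al <- align_to_mean(coords, w)
    aligned <- al$aligned
    mean_x <- al$mean
  } else {
    aligned <- lapply(coords, function(x) superpose(x, coords[[1]], w)$aligned)
    mean_x <- Reduce(`+`, aligned) / length(aligned)
  }
  msf <- Reduce(`+`, lapply(aligned, function(x) {
    rowSums((x - mean_x)^2)
  })) / length(aligned)
  resid <- traj$topology$resid[sel]
  per_res <- tapply(msf * w, resid, sum) / tapply(w, resid, sum)
  out <- data.frame(resid = as.integer(names(per_res)),
                    rmsf_nm = sqrt(as.numeric(per_res)))
  out <- out[order(match(out$resid, resid)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("RmsfProfile", "data.frame"))
}

#' Common principal component analysis over pooled trajectories
#'
#' Superposes every frame of every trajectory onto the pooled iterated
#' mean structure, diagonalizes the covariance of the pooled 3N
#' coordinate vectors, and projects each trajectory's frames onto the
#' shared components, so conformational spans of different simulations
#' are directly comparable in one PC1/PC2 plane.
#'
#' @param trajs list of [trajectory()] objects.
#' @param sel one selection applied to every trajectory, or a list of
#'   per-trajectory selections of identical size.
#' @param mass_weighted use masses as superposition weights.
#' @return object of class `PcaResult`: list with `mean_structure`,
#'   `components` (rows = PCs over 3N coordinates), `eigenvalues` (nm^2,
#'   descending), `projections` (data.frame: `traj`, `frame`, `pc1`,
#'   `pc2`), `total_variance`.
#' @export
common_pca <- function(trajs, sel, mass_weighted = TRUE) {
  if (inherits(trajs, "Trajectory")) trajs <- list(trajs)
  sels <- if (is.list(sel) && !inherits(sel, "Selection")) sel
          else rep(list(sel), length(trajs))
  sizes <- vapply(sels, length, integer(1))
  if (length(unique(sizes)) != 1) {
    stop_pf("selection size differs across trajectories (%s)",
            paste(sizes, collapse = ", "))
  }
  labels <- if (!is.null(names(trajs))) names(trajs)
            else paste0("traj", seq_along(trajs))
  coords <- list()
  src <- integer(0)
  frm <- integer(0)
  for (k in seq_along(trajs)) {
    nf <- n_frames(trajs[[k]])
    for (i in seq_len(nf)) {
      coords[[length(coords) + 1]] <- coords_at(trajs[[k]], sels[[k]], i)
    }
    src <- c(src, rep(k, nf))
    frm <- c(frm, seq_len(nf))
  }
  n_at <- sizes[1]
  if (length(coords) <= 3 * n_at) {
    warn_pf("pooled frame count (%d) <= 3 x n_atoms (%d): PCA poorly determined",
            length(coords), 3 * n_at)
  }
  w <- weights_for(trajs[[1]]$topology, sels[[1]], mass_weighted)
  al <- align_to_mean(coords, w)
  X <- do.call(rbind, lapply(al$aligned, function(x) as.vector(t(x))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  covm <- crossprod(Xc) / (nrow(Xc) - 1)
  eig <- eigen(covm, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  proj <- Xc %*% eig$vectors[, 1:2, drop = FALSE]
  structure(list(
    mean_structure = matrix(mu, ncol = 3, byrow = TRUE),
    components = t(eig$vectors),
    eigenvalues = ev,
    projections = data.frame(traj = labels[src], frame = frm,
                             pc1 = proj[, 1], pc2 = proj[, 2],
                             stringsAsFactors = FALSE),
    total_variance = sum(diag(covm))), class = "PcaResult")
}

#' Area spanned by PC1/PC2 projections
#'
#' Convex-hull area of the projected conformations: a parameter-free
#' scalar for comparing how much of the essential subspace two
#' simulations explore.
#'
#' @param projections two-column matrix or data.frame of (PC1, PC2)
#'   points (nm).
#' @return hull area in nm^2; 0 with a warning for fewer than 3 distinct
#'   or collinear points.
#' @export
pc_span_area <- function(projections) {
  pts <- as.matrix(projections[, 1:2, drop = FALSE])
  pts <- unique(pts)
  if (nrow(pts) < 3) {
    warn_pf("fewer than 3 distinct points: span area 0")
    return(0)
  }
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(hull) < 3) {
    warn_pf("collinear points: span area 0")
    return(0)
  }
  x <- pts[hull, 1]
  y <- pts[hull, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
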