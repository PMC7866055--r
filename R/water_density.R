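#' z-averaged water number density inside a lateral cylinder
#'
#' Bins waters by z within a cylinder of `lateral_radius` about a
#' per-frame axis centre (the x/y COM of `axis_sel`, or a fixed point),
#' and normalizes counts by the cylindrical bin volume. The bin-wise
#' integral (density x bin volume) equals the mean water count inside
#' the analysis region by construction.
#'
#' @param traj a [trajectory()].
#' @param waters selection of one tracking atom per water molecule.
#' @param axis_sel selection defining the per-frame (x, y) axis centre via
#'   its COM; ignored when `axis_center` is given.
#' @param axis_center fixed (x, y) axis centre (nm).
#' @param lateral_radius cylinder radius (nm); default 2, matching the
#'   pore-region radius used for permeability.
#' @param bin_width z bin width (nm).
#' @param z_range z interval covered by the bins; the frame-1 box z edge
#'   when `NULL`.
#' @return object of class `DensityProfile`: data.frame with `z_nm` (bin
#'   centres) and `density_per_nm3`, with attributes `bin_width`,
#'   `lateral_radius`, `mean_count`.
#' @export
z_density_profile <- function(traj, waters, axis_sel = NULL,
                              axis_center = NULL, lateral_radius = 2,
                              bin_width = 0.1, z_range = NULL) {
  if (length(waters) == 0) stop_pf("empty water selection")
  if (lateral_radius <= 0 || bin_width <= 0) {
    stop_pf("lateral_radius and bin_width must be > 0")
  }
  if (is.null(z_range)) z_range <- c(0, traj$box[1, 3])
  nb <- max(1L, as.integer(round(diff(z_range) / bin_width)))
  bin_width <- diff(z_range) / nb
  edges <- seq(z_range[1], z_range[2], length.out = nb + 1)
  nf <- n_frames(traj)
  counts <- numeric(nb)
  centers <- if (!is.null(axis_center)) {
    matrix(axis_center[1:2], nf, 2, byrow = TRUE)
  } else if (!is.null(axis_sel)) {
    com_series(traj, axis_sel)[, 1:2, drop = FALSE]
  } else {
    stop_pf("supply axis_sel or axis_center")
  }
  for (i in seq_len(nf)) {
    x <- coords_at(traj, waters, i)
    dxy <- min_image(cbind(x[, 1] - centers[i, 1], x[, 2] - centers[i, 2], 0),
                     traj$box[i, ])
    inside <- dxy[, 1]^2 + dxy[, 2]^2 < lateral_radius^2 &
      x[, 3] >= z_range[1] & x[, 3] < z_range[2]
    if (any(inside)) {
      b <- pmin(nb, 1L + floor((x[inside, 3] - z_range[1]) / bin_width))
      tb <- tabulate(b, nbins = nb)
      counts <- counts + tb
    }
  }
  vol <- pi * lateral_radius^2 * bin_width
  out <- data.frame(z_nm = (edges[-1] + edges[-(nb + 1)]) / 2,
                    density_per_nm3 = counts / nf / vol)
  attr(out, "bin_width") <- bin_width
  attr(out, "lateral_radius") <- lateral_radius
  attr(out, "mean_count") <- sum(counts) / nf
  class(out) <- c("DensityProfile", "data.frame")
  out
}

#' Occupancy volume map
#'
#' Fraction of frames in which each voxel of an axis-aligned grid
#' contains at least one selected atom: a normalized 0-1 map whose
#' isosurfaces (e.g. at isovalue 0.2) visualize time-averaged water
#' volumes.
#'
#' @param traj a [trajectory()].
#' @param sel atom selection.
#' @param region list with `min` and `max` (length-3, nm) bounding the
#'   grid; must lie inside the simulation box.
#' @param spacing voxel edge (nm).
#' @return object of class `OccupancyGrid`: list with `origin`,
#'   `spacing`, `values` (3-d array of occupancy fractions).
#' @export
occupancy_grid <- function(traj, sel, region, spacing = 0.1) {
  if (spacing <= 0) stop_pf("spacing must be > 0")
  lo <- as.numeric(region$min)
  hi <- as.numeric(region$max)
  if (any(hi <= lo)) stop_pf("region max must exceed min")
  if (any(lo < 0) || any(hi > traj$box[1, ] + 1e-9)) {
    stop_pf("region lies outside the simulation box")
  }
  nd <- pmax(1L, as.integer(round((hi - lo) / spacing)))
  sp <- (hi - lo) / nd  # exact cover of the configured region
  nf <- n_frames(traj)
  acc <- array(0L, dim = nd)
  for (i in seq_len(nf)) {
    x <- coords_at(traj, sel, i)
    ok <- x[, 1] >= lo[1] & x[, 1] < hi[1] & x[, 2] >= lo[2] &
      x[, 2] < hi[2] & x[, 3] >= lo[3] & x[, 3] < hi[3]
    if (!any(ok)) next
    v <- cbind(pmin(nd[1], 1L + floor((x[ok, 1] - lo[1]) / sp[1])),
               pmin(nd[2], 1L + floor((x[ok, 2] - lo[2]) / sp[2])),
               pmin(nd[3], 1L + floor((x[ok, 3] - lo[3]) / sp[3])))
    v <- unique(v)
    acc[v] <- acc[v] + 1L
  }
  structure(list(origin = lo, spacing = sp, values = acc / nf),
            class = "OccupancyGrid")
}

#' Test continuity of a water channel in an occupancy map
#'
#' Thresholds the occupancy grid at `isovalue`, finds 6-neighbour
#' connected components, and reports whether any component touches both
#' z faces of the region (a continuous channel along the pore axis).
#'
#' @param grid an [occupancy_grid()] result with >= 2 voxels along z.
#' @param isovalue occupancy threshold in (0, 1].
#' @return list with `continuous` (logical), `n_components`,
#'   `component_extent_nm` (z extents of each component) and `labels`
#'   (component id array, 0 = below isovalue).
#' @export
is_channel_continuous <- function(grid, isovalue = 0.2) {
  if (!(isovalue > 0 && isovalue <= 1)) stop_pf("isovalue must be in (0, 1]")
  nd <- dim(grid$values)
  if (nd[3] < 2) stop_pf("degenerate grid: need >= 2 voxels along z")
  occ <- grid$values >= isovalue
  labels <- array(0L, dim = nd)
  comp <- 0L
  idx_all <- which(occ)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(cur, nd)
      for (k in 1:3) {
        for (s in c(-1L, 1L)) {
          nb <- ai
          nb[k] <- nb[k] + s
          if (nb[k] < 1 || nb[k] > nd[k]) next
          lin <- nb[1] + nd[1] * (nb[2] - 1 + nd[2] * (nb[3] - 1))
          if (occ[lin] && labels[lin] == 0L) {
            labels[lin] <- comp
            queue <- c(queue, lin)
          }
        }
      }
    }
  }
  spans <- if (comp == 0) logical(0) else vapply(seq_len(comp), function(cc) {
    zs <- which(apply(labels == cc, 3, any))
    zs[1] == 1 && zs[length(zs)] == nd[3]
  }, logical(1))
  extents <- if (comp == 0) numeric(0) else vapply(seq_len(comp), function(cc) {
    zs <- which(apply(labels == cc, 3, any))
    (zs[length(zs)] - zs[1] + 1) * grid$spacing[3]
  }, numeric(1))
  list(continuous = any(spans), n_components = comp,
       component_extent_nm = extents, labels = labels)
}

#' Write an occupancy grid in OpenDX format
#'
#' @param grid an [occupancy_grid()] result.
#' @param path output `.dx` path. Lengths are written in Angstrom, the
#'   unit molecular viewers expect.
#' @export
write_opendx <- function(grid, path) {
  nd <- dim(grid$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "object 1 class gridpositions counts %d %d %d", nd[1], nd[2], nd[3]), con)
  writeLines(sprintf("origin %.6f %.6f %.6f",
                     grid$origin[1] * 10, grid$origin[2] * 10,
                     grid$origin[3] * 10), con)
  writeLines(sprintf("delta %.6f 0 0", grid$spacing[1] * 10), con)
  writeLines(sprintf("delta 0 %.6f 0", grid$spacing[2] * 10), con)
  writeLines(sprintf("delta 0 0 %.6f", grid$spacing[3] * 10), con)
  writeLines(sprintf(
    "object 2 class gridconnections counts %d %d %d", nd[1], nd[2], nd[3]), con)
  writeLines(sprintf(
    "object 3 class array type double rank 0 items %d data follows",
    prod(nd)), con)
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z fastest -> dx order
  pad <- ceiling(length(vals) / 3) * 3
  vals <- c(vals, rep(NA, pad - length(vals)))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) {
    paste(sprintf("%.6g", r[!is.na(r)]), collapse = " ")
  })
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  writeLines('object "density" class field', con)
  invisible(path)
}

#' Count water crossing events between two z planes
#'
#' A crossing is logged when a molecule passes from beyond one plane to
#' beyond the other while staying within `lateral_radius` of the axis
#' throughout the traversal (two-plane hysteresis: entering the slab and
#' retreating to the same side counts nothing; leaving the cylinder
#' laterally aborts the attempt). z displacements between consecutive
#' frames are unwrapped by minimum image, so a periodic wrap far from the
#' planes is not mistaken for a traversal. A direct below-to-above
#' transition that never visits the slab between the planes is not
#' counted: at any sane sampling rate such a move is indistinguishable
#' from a path around the periodic boundary.
#'
#' @param traj a [trajectory()].
#' @param waters selection of one tracking atom per molecule.
#' @param z_lower,z_upper plane positions (nm), `z_lower < z_upper`,
#'   inside the box.
#' @param lateral_radius gating radius about the axis (nm).
#' @param axis_sel,axis_center per-frame axis centre, as in
#'   [z_density_profile()].
#' @return object of class `CrossingReport`: list with `n_up`, `n_down`,
#'   `events` (data.frame: `molecule`, `time_ps`, `direction`) and the
#'   plane/gating parameters.
#' @export
count_crossings <- function(traj, waters, z_lower, z_upper,
                            lateral_radius = 2, axis_sel = NULL,
                            axis_center = NULL) {
  if (z_lower >= z_upper) stop_pf("need z_lower < z_upper")
  bz <- traj$box[1, 3]
  if (z_lower < 0 || z_upper > bz) stop_pf("planes outside the box")
  nf <- n_frames(traj)
  nw <- length(waters)
  centers <- if (!is.null(axis_center)) {
    matrix(axis_center[1:2], nf, 2, byrow = TRUE)
  } else if (!is.null(axis_sel)) {
    com_series(traj, axis_sel)[, 1:2, drop = FALSE]
  } else {
    matrix(traj$box[1, 1:2] / 2, nf, 2, byrow = TRUE)
  }
  # states: 0 below, 1 above, 2 transit-from-below, 3 transit-from-above,
  # 4 aborted (left the cylinder laterally while between the planes)
  z <- traj$xyz[waters, 3, 1]
  state <- ifelse(z < z_lower, 0L, ifelse(z > z_upper, 1L, 4L))
  zc <- z  # unwrapped z
  events <- list()
  for (i in 2:nf) {
    dz <- traj$xyz[waters, 3, i] - traj$xyz[waters, 3, i - 1]
    if (any(abs(dz) > bz)) stop_pf("frame spacing too sparse: |dz| > box")
    dz <- dz - bz * round(dz / bz)
    zc <- zc + dz
    # re-anchor unwrapped z to the wrapped coordinate when safely outside
    wrapped <- traj$xyz[waters, 3, i]
    outside <- wrapped < z_lower | wrapped > z_upper
    zc[outside] <- wrapped[outside]
    dxy <- min_image(cbind(traj$xyz[waters, 1, i] - centers[i, 1],
                           traj$xyz[waters, 2, i] - centers[i, 2], 0),
                     traj$box[i, ])
    lat_ok <- dxy[, 1]^2 + dxy[, 2]^2 <= lateral_radius^2
    below <- zc < z_lower
    above <- zc > z_upper
    between <- !below & !above
    up <- above & state == 2L
    down <- below & state == 3L
    if (any(up)) {
      events[[length(events) + 1]] <-
        data.frame(molecule = which(up), time_ps = traj$times[i],
                   direction = "up", stringsAsFactors = FALSE)
    }
    if (any(down)) {
      events[[length(events) + 1]] <-
        data.frame(molecule = which(down), time_ps = traj$times[i],
                   direction = "down", stringsAsFactors = FALSE)
    }
    new_state <- state
    new_state[below] <- 0L
    new_state[above] <- 1L
    enter_b <- between & state == 0L
    enter_a <- between & state == 1L
    new_state[enter_b] <- 2L
    new_state[enter_a] <- 3L
    aborted <- between & (state %in% c(2L, 3L) | state == 4L) & !lat_ok
    new_state[aborted] <- 4L
    state <- new_state
  }
  events <- if (length(events) > 0) do.call(rbind, events)
            else data.frame(molecule = integer(0), time_ps = numeric(0),
                            direction = character(0))
  structure(list(n_up = sum(events$direction == "up"),
                 n_down = sum(events$direction == "down"),
                 z_lower = z_lower, z_upper = z_upper,
                 lateral_radius = lateral_radius, events = events),
            class = "CrossingReport")
}

#' @export
print.CrossingReport <- function(x, ...) {
  cat(sprintf("Crossings between z = %.3f and %.3f nm: %d up, %d down\n",
              x$z_lower, x$z_upper, x$n_up, x$n_down))
  invisible(x)
}
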