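#' Construct a single coordinate frame
#'
#' @param xyz n x 3 coordinate matrix in nm.
#' @param box orthorhombic box edge lengths (Lx, Ly, Lz) in nm.
#' @param time frame time in ps.
#' @return object of class `Frame`.
#' @export
frame <- function(xyz, box, time = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop_pf("xyz must be an n x 3 matrix")
  if (any(!is.finite(xyz))) stop_pf("positions must be finite")
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) {
    stop_pf("box must be three positive edge lengths (orthorhombic)")
  }
  structure(list(xyz = unname(xyz), box = box, time = as.numeric(time)),
            class = "Frame")
}

#' Construct a trajectory
#'
#' Time-ordered coordinate frames over a fixed topology. Coordinates are
#' stored as an `n_atoms` x 3 x `n_frames` array in nm; per-frame boxes as
#' an `n_frames` x 3 matrix.
#'
#' @param topology a [topology()] object.
#' @param xyz `n_atoms` x 3 x `n_frames` array (nm), or a list of n x 3
#'   matrices.
#' @param box per-frame box: length-3 vector (constant box) or
#'   `n_frames` x 3 matrix.
#' @param times frame times in ps, strictly increasing; synthesized as
#'   `(0:(n_frames-1)) * dt` when `NULL`.
#' @param dt nominal inter-frame spacing in ps.
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(topology, xyz, box, times = NULL, dt = NULL) {
  if (is.list(xyz)) {
    nf <- length(xyz)
    xyz <- array(unlist(xyz), dim = c(nrow(xyz[[1]]), 3, nf))
  }
  if (length(dim(xyz)) != 3 || dim(xyz)[2] != 3) {
    stop_pf("xyz must be an n_atoms x 3 x n_frames array")
  }
  if (dim(xyz)[1] != nrow(topology)) {
    stop_pf("coordinate atom count (%d) does not match topology (%d)",
            dim(xyz)[1], nrow(topology))
  }
  nf <- dim(xyz)[3]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  if (nrow(box) != nf) stop_pf("need one box per frame")
  if (any(box <= 0)) stop_pf("box edges must be > 0")
  if (is.null(times)) {
    if (is.null(dt)) dt <- 1
    times <- (seq_len(nf) - 1) * dt
  }
  if (is.null(dt)) dt <- if (nf > 1) times[2] - times[1] else 1
  if (nf > 1 && any(diff(times) <= 0)) {
    stop_pf("frame times must be strictly increasing")
  }
  structure(list(topology = topology, xyz = xyz, box = unname(as.matrix(box)),
                 times = as.numeric(times), dt = as.numeric(dt)),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms, %d frames, t = %.6g..%.6g ps (dt %.6g)\n",
              dim(x$xyz)[1], dim(x$xyz)[3], x$times[1],
              x$times[length(x$times)], x$dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()] object.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Extract one frame of a trajectory
#' @param traj a [trajectory()] object.
#' @param i frame index (1-based).
#' @export
get_frame <- function(traj, i) {
  frame(traj$xyz[, , i, drop = TRUE], traj$box[i, ], traj$times[i])
}

#' Subset trajectory frames
#' @param traj a [trajectory()] object.
#' @param idx frame indices to keep (in order).
#' @export
subset_frames <- function(traj, idx) {
  trajectory(traj$topology, traj$xyz[, , idx, drop = FALSE],
             traj$box[idx, , drop = FALSE], times = traj$times[idx],
             dt = traj$dt)
}
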