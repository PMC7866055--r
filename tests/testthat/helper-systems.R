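# Small in-code fixtures shared across test files.

# Topology of n single-atom waters (OW) plus optional extra residues.
water_topology <- function(n, extra_names = character(0),
                           extra_resnames = character(0),
                           extra_resids = integer(0)) {
  topology(atom_name = c(extra_names, rep("OW", n)),
           resname = c(extra_resnames, rep("SOL", n)),
           resid = c(extra_resids, seq_len(n) + length(extra_resids)))
}

# Trajectory with explicit per-frame coordinates from a list of n x 3
# matrices, constant box.
traj_from_frames <- function(top, frames, box, dt = 1) {
  trajectory(top, frames, box, dt = dt)
}

# A mixed protein-like topology: 3 residues x 3 atoms + 2 waters.
mixed_topology <- function() {
  topology(
    atom_name = c("N", "CA", "C", "N", "CA", "C", "N", "CA", "C",
                  "OW", "OW"),
    resname = c(rep("ALA", 3), rep("ASP", 3), rep("LYS", 3), "SOL", "SOL"),
    resid = c(rep(10L, 3), rep(35L, 3), rep(141L, 3), 200L, 201L))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# Exhaustive rotational-grid RMSD oracle: best weighted RMSD over a grid
# of rotations (coarse global scan + local refinement around the best).
grid_rmsd_oracle <- function(mobile, reference, weights = NULL,
                             n_coarse = 4000, n_refine = 4000) {
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  M <- sweep(mobile, 2, colSums(mobile * w))
  R <- sweep(reference, 2, colSums(reference * w))
  rmsd_rot <- function(rot) sqrt(sum(w * rowSums((M %*% t(rot) - R)^2)))
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
    matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
             2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
             2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
           3, 3, byrow = TRUE)
  }
  best <- Inf
  best_q <- c(1, 0, 0, 0)
  for (i in seq_len(n_coarse)) {
    q <- rnorm(4)
    v <- rmsd_rot(quat_rot(q))
    if (v < best) {
      best <- v
      best_q <- q / sqrt(sum(q^2))
    }
  }
  scale <- 0.3
  for (i in seq_len(n_refine)) {
    q <- best_q + rnorm(4, sd = scale)
    v <- rmsd_rot(quat_rot(q))
    if (v < best) {
      best <- v
      best_q <- q / sqrt(sum(q^2))
    }
    scale <- scale * 0.999
  }
  best
}

# Brute-force O(N*M) minimum-image contact recount.
brute_contacts <- function(xa, xb, box, cutoff) {
  cnt <- 0L
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      d <- xa[i, ] - xb[j, ]
      d <- d - box * round(d / box)
      if (sum(d^2) < cutoff^2) cnt <- cnt + 1L
    }
  }
  cnt
}
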