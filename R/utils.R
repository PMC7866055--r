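#' @keywords internal
"_PACKAGE"

# Minimum-image convention for an orthorhombic box. `d` is a displacement
# matrix (n x 3) or vector; `box` the edge lengths (nm).
min_image <- function(d, box) {
  if (is.null(dim(d))) d <- matrix(d, ncol = 3)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# Wrap coordinates into [0, box).
wrap_box <- function(x, box) {
  for (k in 1:3) x[, k] <- x[, k] - box[k] * floor(x[, k] / box[k])
  x
}

#' Mass-weighted centre of mass
#'
#' @param xyz n x 3 coordinate matrix (nm).
#' @param mass per-atom masses (amu); unit weights if `NULL`.
#' @return length-3 numeric vector.
#' @keywords internal
com <- function(xyz, mass = NULL) {
  if (is.null(mass)) return(colMeans(xyz))
  colSums(xyz * mass) / sum(mass)
}

# n x 3 coordinate matrix of selected atoms at frame i (robust to
# single-atom selections, where plain `[` would drop dimensions).
coords_at <- function(traj, sel, i) {
  x <- traj$xyz[sel, , i, drop = FALSE]
  dim(x) <- c(length(sel), 3)
  x
}

stop_pf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_pf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic sub-seed derivation: one user-facing seed drives every
# stochastic stage, each stage gets its own stream. Kept below 2^31.
derive_seed <- function(seed, stage) {
  stage_hash <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435L + stage_hash * 97L) %% 2147483587)
}
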