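THREE_LETTER <- c(ALA = "Ala", ARG = "Arg", ASN = "Asn", ASP = "Asp",
                  CYS = "Cys", GLN = "Gln", GLU = "Glu", GLY = "Gly",
                  HIS = "His", ILE = "Ile", LEU = "Leu", LYS = "Lys",
                  MET = "Met", PHE = "Phe", PRO = "Pro", SER = "Ser",
                  THR = "Thr", TRP = "Trp", TYR = "Tyr", VAL = "Val")

residue_label <- function(topology, resid) {
  idx <- residue_atoms(topology, resid)
  rn <- toupper(topology$resname[idx[1]])
  nm <- if (rn %in% names(THREE_LETTER)) THREE_LETTER[[rn]] else rn
  paste0(nm, resid)
}

# Per-frame mass-weighted COM of an atom set: n_frames x 3 matrix.
com_series <- function(traj, idx) {
  m <- traj$topology$mass[idx]
  msum <- sum(m)
  t(apply(traj$xyz[idx, , , drop = FALSE], 3, function(x) {
    colSums(matrix(x, ncol = 3) * m) / msum
  }))
}

#' Residue centre-of-mass distance series
#'
#' Per-frame minimum-image distance between the mass-weighted centres of
#' mass of two whole residues (author numbering). Assumes residues are
#' not split across the periodic boundary.
#'
#' @param traj a [trajectory()].
#' @param residA,residB author residue ids.
#' @return numeric vector of distances (nm), one per frame.
#' @export
residue_com_distance <- function(traj, residA, residB) {
  ca <- com_series(traj, residue_atoms(traj$topology, residA))
  cb <- com_series(traj, residue_atoms(traj$topology, residB))
  d <- cb - ca
  for (k in 1:3) d[, k] <- d[, k] - traj$box[, k] * round(d[, k] / traj$box[, k])
  sqrt(rowSums(d^2))
}

#' Salt-bridge pair-set presets
#'
#' Named residue-pair sets for the matrix and cytosolic gate networks of
#' the UCP2 models and the reference ADP/ATP carrier, in author
#' numbering (acidic partner first).
#'
#' @return named list; each element a 2-column matrix of residue ids.
#' @export
saltbridge_pair_sets <- function() {
  list(
    ucp2_matrix = cbind(acidic = c(35L, 236L, 138L),
                        basic = c(141L, 38L, 239L)),
    ucp2_cytosolic = cbind(acidic = c(198L, 101L, 292L),
                           basic = c(104L, 295L, 201L)),
    ant_matrix = cbind(acidic = c(29L, 231L, 134L),
                       basic = c(137L, 32L, 234L))
  )
}

#' Salt-bridge network analysis
#'
#' Distance time series and occupancy (fraction of frames with distance
#' below the threshold) for each residue pair. Pair sets can be given as
#' a 2-column matrix/list of id pairs or as the name of a preset from
#' [saltbridge_pair_sets()].
#'
#' @param traj a [trajectory()].
#' @param pairs 2-column matrix of (acidic, basic) residue ids, a list of
#'   length-2 vectors, or a preset name.
#' @param threshold formed/broken cutoff on the residue COM distance
#'   (nm). The default 0.6 bisects the gap between formed-bridge
#'   plateaus (~0.4-0.5 nm) and broken states (> 0.8 nm).
#' @return list of `SaltBridgePairResult` objects (data.frame `time_ps`,
#'   `distance_nm` with attributes `pair_label`, `occupancy`,
#'   `threshold`).
#' @export
saltbridge_network <- function(traj, pairs, threshold = 0.6) {
  if (is.character(pairs) && length(pairs) == 1) {
    sets <- saltbridge_pair_sets()
    if (!pairs %in% names(sets)) {
      stop_pf("unknown pair set '%s' (available: %s)", pairs,
              paste(names(sets), collapse = ", "))
    }
    pairs <- sets[[pairs]]
  }
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]
    b <- pairs[i, 2]
    d <- residue_com_distance(traj, a, b)
    res <- data.frame(time_ps = traj$times, distance_nm = d)
    attr(res, "pair_label") <- paste0(residue_label(traj$topology, a), "-",
                                      residue_label(traj$topology, b))
    attr(res, "occupancy") <- mean(d < threshold)
    attr(res, "threshold") <- threshold
    class(res) <- c("SaltBridgePairResult", "data.frame")
    res
  })
}

#' @export
print.SaltBridgePairResult <- function(x, ...) {
  cat(sprintf("Salt bridge %s: occupancy %.3f (threshold %.2f nm, %d frames)\n",
              attr(x, "pair_label"), attr(x, "occupancy"),
              attr(x, "threshold"), nrow(x)))
  invisible(x)
}

#' Three-fold pseudosymmetry of a charged-residue motif
#'
#' Computes the three pairwise COM distance series of a residue triplet
#' (e.g. the conserved negatively charged matrix-side motif) and scores
#' their three-fold pseudosymmetry as the time-averaged coefficient of
#' variation (population SD / mean) of the three per-frame distances.
#' A score of 0 means the triplet is exactly equilateral in every frame.
#'
#' @param traj a [trajectory()].
#' @param triplet three distinct author residue ids.
#' @return object of class `MotifSymmetryResult`: list with
#'   `residue_triplet`, `pairwise_distances` (3-column matrix),
#'   `symmetry_score`.
#' @export
eg_motif_symmetry <- function(traj, triplet) {
  triplet <- as.integer(triplet)
  if (length(triplet) != 3 || anyDuplicated(triplet)) {
    stop_pf("triplet must be three distinct residue ids")
  }
  d12 <- residue_com_distance(traj, triplet[1], triplet[2])
  d13 <- residue_com_distance(traj, triplet[1], triplet[3])
  d23 <- residue_com_distance(traj, triplet[2], triplet[3])
  D <- cbind(d12, d13, d23)
  mu <- rowMeans(D)
  sd_pop <- sqrt(rowMeans((D - mu)^2))
  structure(list(residue_triplet = triplet, pairwise_distances = D,
                 symmetry_score = mean(sd_pop / mu)),
            class = "MotifSymmetryResult")
}
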