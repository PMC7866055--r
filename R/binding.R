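#' Intergroup contact counts over time
#'
#' Per frame, the number of atom pairs (one atom from each group) with
#' minimum-image distance below the cutoff. Pairs are counted
#' individually (the magnitude convention of total-contact traces);
#' `unique_atoms = TRUE` instead counts group-A atoms having at least
#' one contact.
#'
#' @param traj a [trajectory()].
#' @param groupA,groupB disjoint [select_atoms()] selections.
#' @param cutoff contact distance (nm); default 0.35.
#' @param unique_atoms count contacting A atoms instead of pairs.
#' @return object of class `ContactSeries`: data.frame with `time_ps`,
#'   `count`, with attributes `cutoff`, `groupA`, `groupB`.
#' @export
contact_count_series <- function(traj, groupA, groupB, cutoff = 0.35,
                                 unique_atoms = FALSE) {
  if (length(intersect(as.integer(groupA), as.integer(groupB))) > 0) {
    stop_pf("contact groups overlap")
  }
  na <- length(groupA)
  nb <- length(groupB)
  if (na == 0 || nb == 0) stop_pf("empty contact group")
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  counts <- vapply(seq_len(n_frames(traj)), function(i) {
    xa <- coords_at(traj, groupA, i)
    xb <- coords_at(traj, groupB, i)
    d <- min_image(xa[ia, , drop = FALSE] - xb[ib, , drop = FALSE],
                   traj$box[i, ])
    hit <- rowSums(d^2) < cutoff^2
    if (unique_atoms) length(unique(ia[hit])) else sum(hit)
  }, numeric(1))
  out <- data.frame(time_ps = traj$times, count = as.integer(counts))
  attr(out, "cutoff") <- cutoff
  attr(out, "groupA") <- attr(groupA, "label")
  attr(out, "groupB") <- attr(groupB, "label")
  class(out) <- c("ContactSeries", "data.frame")
  out
}

#' Build a replica ensemble
#'
#' Bundles independently started replica trajectories with the analysis
#' window applied to each (as a fraction of its frames). The default
#' window (0.5, 1] keeps the last half of each replica — the convention
#' for 20 ns replicas analyzed over their final 10 ns, the first half
#' being equilibration.
#'
#' @param trajs list of [trajectory()] objects.
#' @param window `(start, end]` fractions of each replica's frames.
#' @return object of class `ReplicaEnsemble`.
#' @export
replica_ensemble <- function(trajs, window = c(0.5, 1)) {
  if (inherits(trajs, "Trajectory")) trajs <- list(trajs)
  if (length(trajs) < 1) stop_pf("need at least one replica")
  if (!(window[1] >= 0 && window[1] < window[2] && window[2] <= 1)) {
    stop_pf("window must satisfy 0 <= start < end <= 1")
  }
  structure(list(replicas = trajs, window = window),
            class = "ReplicaEnsemble")
}

#' Truncate each replica to its analysis window
#'
#' Keeps frames with index fraction in `(start, end]`; e.g. a 20-frame
#' replica with the default last-half window retains frames 11..20.
#'
#' @param ensemble a [replica_ensemble()].
#' @return a `ReplicaEnsemble` with truncated replicas and window reset
#'   to (0, 1].
#' @export
apply_analysis_window <- function(ensemble) {
  stopifnot(inherits(ensemble, "ReplicaEnsemble"))
  w <- ensemble$window
  reps <- lapply(ensemble$replicas, function(tr) {
    nf <- n_frames(tr)
    keep <- which(seq_len(nf) / nf > w[1] & seq_len(nf) / nf <= w[2])
    if (length(keep) == 0) stop_pf("analysis window selects no frames")
    subset_frames(tr, keep)
  })
  replica_ensemble(reps, window = c(0, 1))
}

#' Phosphate-to-arginine binding summary over a replica ensemble
#'
#' For each phosphorus atom and each arginine residue, the distance from
#' the atom to the residue COM is averaged over each replica's analysis
#' window, then summarized across replicas (mean and sample SD, n-1
#' convention). A pair is flagged bound when its ensemble-mean distance
#' is below `bound_cutoff`; the raw distances are always reported so
#' conclusions never depend silently on the flag.
#'
#' @param ensemble a [replica_ensemble()]; the analysis window is
#'   applied internally.
#' @param p_atom_names names of the phosphorus atoms (alpha, beta, gamma
#'   phosphate order).
#' @param arg_resids arginine residue ids; default the conserved
#'   nucleotide-binding triplet 88, 185, 279.
#' @param bound_cutoff bound-flag criterion on the ensemble-mean P-Arg
#'   COM distance (nm).
#' @return object of class `PhosphateBindingSummary`: list with
#'   `per_replica` (data.frame: replica, p_atom, arg_resid, mean_nm) and
#'   `summary` (data.frame: p_atom, arg_resid, mean_nm, sd_nm, bound).
#' @export
phosphate_arginine_summary <- function(ensemble,
                                       p_atom_names = c("PA", "PB", "PG"),
                                       arg_resids = c(88L, 185L, 279L),
                                       bound_cutoff = 0.6) {
  stopifnot(inherits(ensemble, "ReplicaEnsemble"))
  ensemble <- apply_analysis_window(ensemble)
  rows <- list()
  for (r in seq_along(ensemble$replicas)) {
    tr <- ensemble$replicas[[r]]
    for (pa in p_atom_names) {
      pidx <- which(tr$topology$atom_name == pa)
      if (length(pidx) != 1) {
        stop_pf("replica %d: expected exactly one atom named %s (found %d)",
                r, pa, length(pidx))
      }
      for (ar in arg_resids) {
        aidx <- residue_atoms(tr$topology, ar)
        pc <- t(vapply(seq_len(n_frames(tr)), function(i) {
          coords_at(tr, pidx, i)[1, ]
        }, numeric(3)))
        ac <- com_series(tr, aidx)
        d <- pc - ac
        for (k in 1:3) {
          d[, k] <- d[, k] - tr$box[, k] * round(d[, k] / tr$box[, k])
        }
        rows[[length(rows) + 1]] <- data.frame(
          replica = r, p_atom = pa, arg_resid = ar,
          mean_nm = mean(sqrt(rowSums(d^2))), stringsAsFactors = FALSE)
      }
    }
  }
  per_replica <- do.call(rbind, rows)
  agg_mean <- stats::aggregate(mean_nm ~ p_atom + arg_resid, per_replica, mean)
  agg_sd <- stats::aggregate(mean_nm ~ p_atom + arg_resid, per_replica,
                             function(x) if (length(x) > 1) stats::sd(x) else 0)
  summary <- data.frame(p_atom = agg_mean$p_atom,
                        arg_resid = agg_mean$arg_resid,
                        mean_nm = agg_mean$mean_nm,
                        sd_nm = agg_sd$mean_nm,
                        bound = agg_mean$mean_nm < bound_cutoff,
                        stringsAsFactors = FALSE)
  structure(list(per_replica = per_replica, summary = summary,
                 bound_cutoff = bound_cutoff, sd_convention = "sample (n-1)"),
            class = "PhosphateBindingSummary")
}

#' Ligand-to-binding-site salt-bridge monitor
#'
#' COM distance series between a binding-site residue (whole residue or
#' side chain only) and a ligand head group, with occupancy under the
#' threshold — the formation signature contrasting a wild-type arginine
#' site against a mutant where no salt bridge forms.
#'
#' @param traj a [trajectory()].
#' @param site_resid author residue id of the binding-site residue.
#' @param ligand_head selection of the ligand head-group atoms.
#' @param threshold formed/broken cutoff (nm).
#' @param side_chain_only drop backbone atoms (N, CA, C, O) from the
#'   site residue before taking its COM.
#' @return a `SaltBridgePairResult` (see [saltbridge_network()]).
#' @export
binding_site_saltbridge <- function(traj, site_resid, ligand_head,
                                    threshold = 0.6,
                                    side_chain_only = FALSE) {
  if (length(ligand_head) == 0) stop_pf("empty ligand head selection")
  idx <- residue_atoms(traj$topology, site_resid)
  if (side_chain_only) {
    keep <- !(traj$topology$atom_name[idx] %in% c("N", "CA", "C", "O"))
    if (!any(keep)) stop_pf("site residue %d has no side-chain atoms",
                            site_resid)
    idx <- idx[keep]
  }
  ca <- com_series(traj, idx)
  cb <- com_series(traj, as.integer(ligand_head))
  d <- cb - ca
  for (k in 1:3) {
    d[, k] <- d[, k] - traj$box[, k] * round(d[, k] / traj$box[, k])
  }
  dist <- sqrt(rowSums(d^2))
  res <- data.frame(time_ps = traj$times, distance_nm = dist)
  attr(res, "pair_label") <- paste0(residue_label(traj$topology, site_resid),
                                    "-", attr(ligand_head, "label"))
  attr(res, "occupancy") <- mean(dist < threshold)
  attr(res, "threshold") <- threshold
  class(res) <- c("SaltBridgePairResult", "data.frame")
  res
}
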