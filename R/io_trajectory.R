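#' Read a trajectory (multi-frame GRO/PDB or DCD)
#'
#' Frames are returned in file order. Times are taken from the file when
#' present (GRO title `t=` fields) and synthesized as `frame_index * dt`
#' otherwise. XTC is not supported; DCD files carry neither box nor time
#' in the variant written here, so `box`/`dt` come from the caller.
#'
#' @param path file path.
#' @param topology a [topology()] matching the file's atom count.
#' @param format `"gro"`, `"pdb"` or `"dcd"`; inferred from the extension
#'   when `NULL`.
#' @param dt nominal frame spacing (ps) used when the file has no times.
#' @param box fallback per-trajectory box (nm) for formats without one.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, topology, format = NULL, dt = 1,
                            box = NULL) {
  fmt <- detect_format(path, format)
  if (!file.exists(path)) stop_pf("file not found: %s", path)
  if (fmt == "xtc") {
    stop_pf("XTC trajectories are not supported; convert to DCD or multi-frame GRO")
  }
  if (fmt == "gro") {
    blocks <- read_gro_frames(path)
    nat <- vapply(blocks, function(b) nrow(b$xyz), integer(1))
    if (any(nat != nrow(topology))) {
      stop_pf("%s: frame atom count (%d) does not match topology (%d)",
              path, nat[which(nat != nrow(topology))[1]], nrow(topology))
    }
    xyz <- array(unlist(lapply(blocks, function(b) b$xyz)),
                 dim = c(nrow(topology), 3, length(blocks)))
    boxes <- do.call(rbind, lapply(blocks, function(b) b$box))
    times <- vapply(blocks, function(b) b$time, numeric(1))
    if (any(is.na(times))) times <- (seq_along(blocks) - 1) * dt
    return(trajectory(topology, xyz, boxes, times = times, dt = dt))
  }
  if (fmt == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    nat <- ncol(pdb$xyz) / 3
    if (nat != nrow(topology)) {
      stop_pf("%s: frame atom count (%d) does not match topology (%d)",
              path, nat, nrow(topology))
    }
    bx <- parse_cryst1(path)
    if (is.null(bx)) bx <- box
    if (is.null(bx)) stop_pf("%s: no CRYST1 record; supply box=", path)
    nf <- nrow(pdb$xyz)
    xyz <- array(0, dim = c(nat, 3, nf))
    for (i in seq_len(nf)) {
      xyz[, , i] <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE) / 10
    }
    return(trajectory(topology, xyz, bx, dt = dt))
  }
  if (fmt == "dcd") {
    m <- bio3d::read.dcd(path, verbose = FALSE)  # frames x 3N, Angstrom
    nat <- ncol(m) / 3
    if (nat != nrow(topology)) {
      stop_pf("%s: frame atom count (%d) does not match topology (%d)",
              path, nat, nrow(topology))
    }
    if (is.null(box)) stop_pf("DCD carries no box; supply box=")
    nf <- nrow(m)
    xyz <- array(0, dim = c(nat, 3, nf))
    for (i in seq_len(nf)) xyz[, , i] <- matrix(m[i, ], ncol = 3, byrow = TRUE) / 10
    return(trajectory(topology, xyz, box, dt = dt))
  }
  stop_pf("unsupported trajectory format '%s'", fmt)
}

#' Write a trajectory (multi-frame GRO or DCD)
#'
#' GRO output embeds frame times in the title lines and round-trips at
#' the format's 1e-3 nm printed precision. DCD output is the CHARMM/NAMD
#' binary dialect (single-precision Angstrom coordinates, no unit cell).
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @param format `"gro"` or `"dcd"`; inferred from the extension when `NULL`.
#' @export
write_trajectory <- function(traj, path, format = NULL) {
  fmt <- detect_format(path, format)
  if (fmt == "gro") {
    out <- unlist(lapply(seq_len(n_frames(traj)), function(i) {
      format_gro_frame(traj$topology, traj$xyz[, , i], traj$box[i, ],
                       traj$times[i])
    }))
    writeLines(out, path)
  } else if (fmt == "dcd") {
    write_dcd(traj, path)
  } else {
    stop_pf("unsupported trajectory output format '%s'", fmt)
  }
  invisible(path)
}

# CHARMM-style DCD writer (little-endian, Fortran record markers,
# single-precision Angstrom coordinates, no crystal records).
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  nat <- dim(traj$xyz)[1]
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  icntrl <- integer(20)
  icntrl[1] <- nf       # NSET
  icntrl[2] <- 1        # ISTART
  icntrl[3] <- 1        # NSAVC
  icntrl[20] <- 24      # CHARMM version stamp
  wint(84); writeChar("CORD", con, nchars = 4, eos = NULL); wint(icntrl); wint(84)
  title <- sprintf("%-80s", "poreflow trajectory")
  wint(4 + 80)  # title record: ntitle int + one 80-char line
  wint(1); writeChar(title, con, nchars = 80, eos = NULL); wint(4 + 80)
  wint(4); wint(nat); wint(4)
  for (i in seq_len(nf)) {
    for (k in 1:3) {
      wint(4 * nat)
      writeBin(as.numeric(traj$xyz[, k, i] * 10), con, size = 4,
               endian = "little")
      wint(4 * nat)
    }
  }
  invisible(path)
}
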