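# GRO coordinate files (GROMACS fixed-width dialect, nm units). Handles
# single- and multi-frame files; multi-frame GRO is the plain-text fixture
# dialect used throughout the test suite.

parse_gro_block <- function(lines, offset, path) {
  title <- lines[offset]
  nat <- suppressWarnings(as.integer(trimws(lines[offset + 1])))
  if (is.na(nat) || nat < 1) {
    stop_pf("%s: malformed atom-count record at line %d", path, offset + 1)
  }
  if (length(lines) < offset + 1 + nat + 1) {
    return(NULL)  # truncated block; caller warns and drops
  }
  at <- lines[offset + 1 + seq_len(nat)]
  resid <- suppressWarnings(as.integer(substr(at, 1, 5)))
  resname <- trimws(substr(at, 6, 10))
  atname <- trimws(substr(at, 11, 15))
  x <- suppressWarnings(as.numeric(substr(at, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(at, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(at, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0) {
    stop_pf("%s: malformed atom record at line %d", path, offset + 1 + bad[1])
  }
  boxline <- suppressWarnings(as.numeric(strsplit(
    trimws(lines[offset + 2 + nat]), "[[:space:]]+")[[1]]))
  if (length(boxline) < 3 || any(is.na(boxline))) {
    stop_pf("%s: malformed box record at line %d", path, offset + 2 + nat)
  }
  if (length(boxline) > 3 && any(abs(boxline[-(1:3)]) > 1e-9)) {
    stop_pf("%s: triclinic box not supported (off-diagonal box elements)", path)
  }
  tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
  list(resid = resid, resname = resname, atom_name = atname,
       xyz = cbind(x, y, z), box = boxline[1:3],
       time = if (length(tm) == 2) as.numeric(tm[2]) else NA_real_,
       next_offset = offset + 3 + nat)
}

read_gro_frames <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  off <- 1
  while (off <= length(lines) && nzchar(trimws(paste(lines[off], "")))) {
    b <- parse_gro_block(lines, off, path)
    if (is.null(b)) {
      warn_pf("%s: truncated final frame dropped", path)
      break
    }
    blocks[[length(blocks) + 1]] <- b
    off <- b$next_offset
    while (off <= length(lines) && !nzchar(trimws(lines[off]))) off <- off + 1
  }
  if (length(blocks) == 0) stop_pf("%s: no frames found", path)
  blocks
}

format_gro_frame <- function(topology, xyz, box, time) {
  title <- sprintf("poreflow, t= %.5f", time)
  n <- nrow(topology)
  atomnr <- ((seq_len(n) - 1) %% 99999) + 1
  resnr <- ((topology$resid - 1) %% 99999) + 1
  at <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                resnr, substr(topology$resname, 1, 5),
                substr(topology$atom_name, 1, 5), atomnr,
                xyz[, 1], xyz[, 2], xyz[, 3])
  c(title, sprintf("%5d", n), at,
    sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
}
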