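detect_format <- function(path, format = NULL) {
  if (!is.null(format)) return(tolower(format))
  tolower(tools::file_ext(path))
}

parse_cryst1 <- function(path) {
  hdr <- readLines(path, n = 200)
  cl <- grep("^CRYST1", hdr, value = TRUE)
  if (length(cl) == 0) return(NULL)
  v <- suppressWarnings(as.numeric(c(
    substr(cl[1], 7, 15), substr(cl[1], 16, 24), substr(cl[1], 25, 33),
    substr(cl[1], 34, 40), substr(cl[1], 41, 47), substr(cl[1], 48, 54))))
  if (any(is.na(v))) stop_pf("%s: malformed CRYST1 record", path)
  if (any(abs(v[4:6] - 90) > 1e-3)) {
    stop_pf("%s: triclinic box not supported (cell angles != 90)", path)
  }
  v[1:3] / 10  # Angstrom -> nm
}

topology_from_pdb <- function(pdb, mass_table = NULL, default_mass = NA_real_) {
  topology(atom_name = pdb$atom$elety, resname = pdb$atom$resid,
           resid = pdb$atom$resno, mass_table = mass_table,
           default_mass = default_mass)
}

#' Read a molecular structure (PDB or GRO)
#'
#' Reads topology plus a single coordinate frame. GRO coordinates are
#' native nm; PDB coordinates (Angstrom) are converted to nm on read. The
#' box is taken from the GRO box line or the PDB CRYST1 record; only
#' orthorhombic boxes are supported. Masses are assigned from the element
#' inferred from the atom name, overridable via `mass_table`.
#'
#' @param path file path.
#' @param format `"pdb"` or `"gro"`; inferred from the extension when `NULL`.
#' @param mass_table named numeric vector of element masses (amu) merged
#'   over the built-in table.
#' @param default_mass fallback mass for unknown elements; unknown
#'   elements are an error when `NA` (the default).
#' @param box fallback box (nm) when the file carries none.
#' @return list with elements `topology` ([topology()]) and `frame`
#'   ([frame()]).
#' @export
read_structure <- function(path, format = NULL, mass_table = NULL,
                           default_mass = NA_real_, box = NULL) {
  fmt <- detect_format(path, format)
  if (!file.exists(path)) stop_pf("file not found: %s", path)
  if (fmt == "gro") {
    b <- read_gro_frames(path)[[1]]
    top <- topology(b$atom_name, b$resname, b$resid,
                    mass_table = mass_table, default_mass = default_mass)
    fr <- frame(b$xyz, b$box, if (is.na(b$time)) 0 else b$time)
  } else if (fmt == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    top <- topology_from_pdb(pdb, mass_table, default_mass)
    bx <- parse_cryst1(path)
    if (is.null(bx)) bx <- box
    if (is.null(bx)) stop_pf("%s: no CRYST1 record; supply box=", path)
    fr <- frame(matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10, bx, 0)
  } else {
    stop_pf("unsupported structure format '%s'", fmt)
  }
  if (nrow(fr$xyz) != nrow(top)) stop_pf("%s: atom count mismatch", path)
  list(topology = top, frame = fr)
}

#' Write a molecular structure (PDB or GRO)
#'
#' @param topology a [topology()] object.
#' @param fr a [frame()] object (nm; PDB output converts to Angstrom).
#' @param path output path.
#' @param format `"pdb"` or `"gro"`; inferred from the extension when `NULL`.
#' @export
write_structure <- function(topology, fr, path, format = NULL) {
  fmt <- detect_format(path, format)
  if (fmt == "gro") {
    writeLines(format_gro_frame(topology, fr$xyz, fr$box, fr$time), path)
  } else if (fmt == "pdb") {
    bio3d::write.pdb(file = path, xyz = as.vector(t(fr$xyz * 10)),
                     resno = topology$resid, resid = topology$resname,
                     elety = topology$atom_name)
    cryst <- sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      fr$box[1] * 10, fr$box[2] * 10, fr$box[3] * 10, 90, 90, 90)
    writeLines(c(cryst, readLines(path)), path)
  } else {
    stop_pf("unsupported structure format '%s'", fmt)
  }
  invisible(path)
}
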