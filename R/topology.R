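ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  NA. = 22.990, CL = 35.45, MG = 24.305, K = 39.098, CA. = 40.078,
  FE = 55.845, ZN = 65.38, F = 18.998, BR = 79.904, I = 126.904
)

DEFAULT_WATER_RESNAMES <- c("SOL", "HOH", "WAT", "TIP3")

# Guess the element from an atom name following the PDB convention:
# try the two-character element first (for Na/Cl/Mg/... which are
# spelled out), otherwise fall back to the first alphabetic character.
infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", atom_name)))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% c("NA", "CL", "MG", "FE", "ZN", "BR"), two, one)
}

element_mass <- function(element, mass_table = NULL, default_mass = NA_real_) {
  key <- element
  key[key == "NA"] <- "NA."
  tbl <- ELEMENT_MASSES
  if (!is.null(mass_table)) tbl[names(mass_table)] <- mass_table
  m <- unname(tbl[key])
  miss <- is.na(m)
  if (any(miss)) {
    if (is.na(default_mass)) {
      stop_pf("unknown element(s) %s; supply mass_table= or default_mass=",
              paste(unique(element[miss]), collapse = ", "))
    }
    m[miss] <- default_mass
  }
  m
}

#' Build a molecular topology
#'
#' A topology holds the static atom/residue bookkeeping every analysis
#' relies on: atom names, residue names, author-assigned residue ids and
#' atomic masses (amu). Consecutive atoms sharing the same
#' (residue id, residue name) pair form one residue; residues also get a
#' contiguous internal index so both the author numbering used in
#' configuration files (e.g. "R60", "Asp35") and a positional index are
#' available.
#'
#' @param atom_name character vector of atom names.
#' @param resname residue name per atom.
#' @param resid author-assigned residue id per atom (integer).
#' @param mass per-atom mass in amu; inferred from the element implied by
#'   `atom_name` when `NULL`.
#' @param mass_table named numeric vector overriding element masses.
#' @param default_mass fallback mass for unrecognized elements; by default
#'   unknown elements are an error.
#' @return object of class `Topology`: a data.frame with columns
#'   `atom_name`, `resname`, `resid`, `residue_index`, `mass`.
#' @export
topology <- function(atom_name, resname, resid, mass = NULL,
                     mass_table = NULL, default_mass = NA_real_) {
  n <- length(atom_name)
  stopifnot(length(resname) == n, length(resid) == n)
  resid <- as.integer(resid)
  if (is.null(mass)) {
    mass <- element_mass(infer_element(atom_name), mass_table, default_mass)
  }
  if (length(mass) != n) stop_pf("mass must have one entry per atom")
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop_pf("all atom masses must be finite and > 0")
  }
  key <- paste(resid, resname)
  new_res <- c(TRUE, key[-1] != key[-n])
  top <- data.frame(
    atom_name = as.character(atom_name),
    resname = as.character(resname),
    resid = resid,
    residue_index = cumsum(new_res),
    mass = as.numeric(mass),
    stringsAsFactors = FALSE
  )
  class(top) <- c("Topology", "data.frame")
  top
}

n_atoms <- function(topology) nrow(topology)

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d residues\n",
              nrow(x), max(x$residue_index)))
  invisible(x)
}

# Atom rows (1-based) of a residue identified by author id.
residue_atoms <- function(topology, resid, resname = NULL) {
  hit <- topology$resid == resid
  if (!is.null(resname)) hit <- hit & topology$resname == resname
  idx <- which(hit)
  if (length(idx) == 0) stop_pf("residue id %s not found in topology", resid)
  idx
}
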