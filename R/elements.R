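# Element symbols and atom-name -> element inference.

# Symbols with a Cromer-Mann entry shipped in inst/extdata/cromer_mann.tsv,
# plus the full set of recognized one/two letter symbols for validation.
.SWX_KNOWN_ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Mo", "Ru", "Rh", "Pd", "Ag", "Cd", "Sn", "Sb", "Te", "I",
  "Xe", "Cs", "Ba", "W", "Pt", "Au", "Hg", "Pb", "Bi", "U"
)

# Marker for atoms whose element could not be determined.
.SWX_UNKNOWN_ELEMENT <- "X"

.SWX_STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)
.SWX_STANDARD_NT <- c("A", "C", "G", "U", "T", "DA", "DC", "DG", "DT", "DU")
.SWX_WATER_RESNAMES <- c("HOH", "WAT", "SOL", "TIP3", "TIP", "SPC", "H2O")

.swx_is_polymer_resname <- function(resname) {
  toupper(resname) %in% c(.SWX_STANDARD_AA, .SWX_STANDARD_NT)
}

.swx_is_water_resname <- function(resname) {
  toupper(resname) %in% .SWX_WATER_RESNAMES
}

.swx_normalize_element <- function(sym) {
  sym <- gsub("[^A-Za-z]", "", sym)
  out <- character(length(sym))
  nz <- nchar(sym) > 0L
  out[!nz] <- ""
  s <- sym[nz]
  cand <- paste0(toupper(substr(s, 1, 1)), tolower(substr(s, 2, nchar(s))))
  out[nz] <- cand
  out
}

# Two-letter element symbols that also occur as leading characters of common
# organic atom names ("CA", "CD", "NE", ...).  They are taken as elements only
# when the residue is not a standard polymer residue; inside amino acids and
# nucleotides "CA" is always the alpha carbon, "NE" a nitrogen, and so on.
.SWX_AMBIGUOUS_TWO_LETTER <- c("Ca", "Cd", "Ce", "Co", "Cs", "Cu", "Na",
                               "Nb", "Nd", "Ne", "Ni", "Os", "Hg", "Ho")

#' Infer an element symbol from a PDB atom name
#'
#' Follows PDB v3 column conventions: a name whose first column (column 13 of
#' the record) is occupied may start a two-letter element (`"FE"`, `"ZN"`),
#' while names starting in column 14 are one-letter elements possibly followed
#' by remoteness indicators (`" CA "` is a carbon).  Leading digits (hydrogen
#' names such as `"1HB"`) are stripped.  Two-letter symbols that collide with
#' common organic names (see `"CA"`) are only accepted outside standard
#' amino-acid/nucleotide residues.
#'
#' @param name Atom name, ideally the raw 4-character PDB field (alignment is
#'   used when available).
#' @param resname Residue name, used to disambiguate two-letter collisions.
#' @return Element symbol, or `"X"` when nothing could be inferred.
#' @export
infer_element <- function(name, resname = "") {
  mapply(function(nm, rn) {
    raw <- nm
    padded <- nchar(raw) == 4L
    col13 <- if (padded) substr(raw, 1, 1) else ""
    stripped <- gsub("[^A-Za-z].*$", "", gsub("^[0-9 ]+", "", raw))
    if (nchar(stripped) == 0L) return(.SWX_UNKNOWN_ELEMENT)
    two <- .swx_normalize_element(substr(stripped, 1, 2))
    one <- .swx_normalize_element(substr(stripped, 1, 1))
    two_ok <- nchar(stripped) >= 2L && two %in% .SWX_KNOWN_ELEMENTS
    if (two_ok) {
      ambiguous <- two %in% .SWX_AMBIGUOUS_TWO_LETTER
      # With full-width names, elements start in column 13; a blank there
      # means the name is a one-letter element plus remoteness codes.
      starts_col13 <- !padded || col13 != " "
      if (starts_col13 && !(ambiguous && .swx_is_polymer_resname(rn)) &&
          !(ambiguous && .swx_is_water_resname(rn))) {
        return(two)
      }
    }
    if (one %in% .SWX_KNOWN_ELEMENTS) return(one)
    .SWX_UNKNOWN_ELEMENT
  }, name, resname, USE.NAMES = FALSE)
}
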