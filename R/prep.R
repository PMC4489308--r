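# Structure clean-up: crystallization-agent detection, selenomethionine
# replacement, and form-factor element assignment.

# Residue names that always indicate crystallization agents (glycerol,
# B-nonylglucoside, B-octylglucoside, polyethylene glycols).
.SWX_AGENT_BLACKLIST <- c("GOL", "BNG", "BOG", "PG", "PE", "PGE")

.SWX_METALS <- c("Na", "Mg", "K", "Ca", "Mn", "Fe", "Cu", "Zn")

#' Classify hetero molecules as ligands or crystallization agents
#'
#' PDB files carry no reliable flag separating biologically relevant ligands
#' from crystallization agents, so a rule set combining residue name, size
#' and contacts is applied per hetero molecule.  Blacklisted residue names
#' (`GOL`, `BNG`, `BOG`, `PG`, `PE`, `PGE`) are removed unconditionally
#' (checked first, so a long PEG is removed despite its size).  Otherwise a
#' molecule is kept iff it (i) is covalently bonded to the biomolecule,
#' (ii) forms more than 2.5 contacts per heavy atom to the biomolecule at a
#' 3.5 Angstrom heavy-atom cutoff, (iii) has more than 20 heavy atoms, or
#' (iv) is named HEM (a heme).  Everything else is removed.
#'
#' The biomolecule is the set of non-hetero (polymer) atoms.  "Contact" means
#' a heavy-atom pair, one ligand / one biomolecule atom, within 3.5 Angstrom;
#' hydrogens are excluded from both the contact and heavy-atom counts.
#' Covalent attachment is a heavy-atom pair closer than 1.9 Angstrom (2.4
#' when either partner is S, Se or a metal).
#'
#' @param structure A `swx_structure` with at least one polymer (non-hetero)
#'   atom.
#' @return A tibble with one row per hetero molecule: `molecule_index`,
#'   `resname`, `n_heavy`, `decision` (`keep`/`remove`) and `matched_rule`
#'   (`blacklist-name`, `covalent`, `contacts`, `size`, `heme-name`,
#'   `default-remove`).
#' @export
classify_hetero_molecules <- function(structure) {
  a <- structure$atoms
  mol <- structure$molecules
  bio_idx <- which(!a$hetero)
  if (!length(bio_idx)) {
    stop("structure has no polymer (non-hetero) atoms; ",
         "contact rules are undefined")
  }
  bio_heavy <- bio_idx[a$element[bio_idx] != "H"]
  bio_xyz <- as.matrix(a[bio_heavy, c("x", "y", "z")])
  bio_el <- a$element[bio_heavy]
  het_mols <- sort(unique(mol[a$hetero]))
  # molecules mixing polymer and hetero atoms (covalently merged via CONECT)
  # are not classified: they are already part of the biomolecule
  het_mols <- het_mols[vapply(het_mols, function(m) all(a$hetero[mol == m]),
                              logical(1))]
  rows <- lapply(het_mols, function(m) {
    idx <- which(mol == m)
    heavy <- idx[a$element[idx] != "H"]
    resname <- toupper(a$resname[idx[1]])
    n_heavy <- length(heavy)
    rule <- NULL
    if (resname %in% .SWX_AGENT_BLACKLIST) {
      rule <- "blacklist-name"; keep <- FALSE
    } else {
      xyz <- as.matrix(a[heavy, c("x", "y", "z")])
      el <- a$element[heavy]
      dmin <- Inf; contacts <- 0L; covalent <- FALSE
      if (n_heavy > 0L && nrow(bio_xyz) > 0L) {
        for (i in seq_len(n_heavy)) {
          dv <- sqrt(colSums((t(bio_xyz) - xyz[i, ])^2))
          contacts <- contacts + sum(dv <= 3.5)
          cutoff <- ifelse(el[i] %in% c("S", "Se", .SWX_METALS) |
                             bio_el %in% c("S", "Se", .SWX_METALS),
                           2.4, 1.9)
          if (any(dv < cutoff)) covalent <- TRUE
        }
      }
      if (covalent) {
        rule <- "covalent"; keep <- TRUE
      } else if (n_heavy > 0L && contacts / n_heavy > 2.5) {
        rule <- "contacts"; keep <- TRUE
      } else if (n_heavy > 20L) {
        rule <- "size"; keep <- TRUE
      } else if (resname == "HEM") {
        rule <- "heme-name"; keep <- TRUE
      } else {
        rule <- "default-remove"; keep <- FALSE
      }
    }
    tibble::tibble(molecule_index = m, resname = resname, n_heavy = n_heavy,
                   decision = if (keep) "keep" else "remove",
                   matched_rule = rule)
  })
  if (!length(rows)) {
    return(tibble::tibble(molecule_index = integer(), resname = character(),
                          n_heavy = integer(), decision = character(),
                          matched_rule = character()))
  }
  do.call(rbind, rows)
}

#' Apply a ligand-handling policy to a structure
#'
#' Three modes: `"default"` keeps ligands and removes detected
#' crystallization agents (per [classify_hetero_molecules()]), `"keep-all"`
#' keeps every hetero molecule, `"remove-all"` removes every hetero molecule
#' that is not covalently merged into the biomolecule.
#'
#' @param structure A `swx_structure`.
#' @param mode `"default"`, `"keep-all"` or `"remove-all"`.
#' @return The filtered `swx_structure` with an attribute `"verdicts"`
#'   (the classification tibble, for the run log).
#' @export
apply_ligand_policy <- function(structure,
                                mode = c("default", "keep-all",
                                         "remove-all")) {
  mode <- match.arg(mode)
  if (mode == "keep-all") {
    attr(structure, "verdicts") <- NULL
    return(structure)
  }
  verdicts <- classify_hetero_molecules(structure)
  drop_mols <- if (mode == "remove-all") {
    verdicts$molecule_index
  } else {
    verdicts$molecule_index[verdicts$decision == "remove"]
  }
  out <- .swx_subset_structure(structure,
                               !(structure$molecules %in% drop_mols))
  attr(out, "verdicts") <- verdicts
  out
}

.swx_subset_structure <- function(structure, keep) {
  atoms <- structure$atoms[keep, , drop = FALSE]
  mol <- structure$molecules[keep]
  structure(list(atoms = atoms,
                 molecules = as.integer(factor(mol, levels = unique(mol))),
                 box = structure$box),
            class = "swx_structure")
}

#' Replace selenomethionine by methionine
#'
#' Selenomethionine is introduced to aid phasing and is typically absent from
#' the scattering sample.  When enabled, every MSE residue is renamed MET and
#' its selenium renamed to the corresponding sulfur (SE -> SD, element
#' Se -> S); coordinates and atom counts are unchanged.
#'
#' @param structure A `swx_structure`.
#' @param enabled If `FALSE`, the structure is returned unchanged.
#' @return The (possibly modified) `swx_structure`.
#' @export
replace_selenomethionine <- function(structure, enabled = TRUE) {
  if (!enabled) return(structure)
  a <- structure$atoms
  mse <- toupper(a$resname) == "MSE"
  if (!any(mse)) return(structure)
  se <- mse & a$element == "Se"
  a$resname[mse] <- "MET"
  a$name[se] <- "SD"
  a$name_raw[se] <- " SD "
  a$element[se] <- "S"
  a$hetero[mse] <- FALSE  # MET is a standard residue
  structure$atoms <- a
  structure
}

#' Assign a form-factor table key to every atom
#'
#' Maps each atom to its Cromer-Mann table key: atoms of water residues to
#' the water species `OW`/`HW`, everything else to its element symbol.  Ions
#' always keep their own element for the form factor, even where a simulation
#' engine would substitute them by a parameterized surrogate.  The returned
#' report mirrors a dummy topology: it lists, atom by atom, which element and
#' hence which form factor was assigned, so unusual atoms can be audited.
#'
#' @param structure A `swx_structure`.
#' @param table A `swx_fftable` used to validate that every key has an entry.
#' @return A tibble with columns `serial`, `name`, `resname`, `resid`,
#'   `element`, `ff_key`.
#' @export
assign_form_factor_elements <- function(structure,
                                        table = load_form_factor_table()) {
  a <- structure$atoms
  keys <- water_aware_keys(structure)
  missing <- !(keys %in% names(table$entries))
  if (any(missing)) {
    i <- which(missing)[1]
    stop("no form-factor entry for atom serial ", a$serial[i],
         " (", a$name[i], " in ", a$resname[i], " ", a$resid[i],
         "): element '", a$element[i], "'")
  }
  tibble::tibble(serial = a$serial, name = a$name, resname = a$resname,
                 resid = a$resid, element = a$element, ff_key = keys)
}
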