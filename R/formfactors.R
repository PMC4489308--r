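# Atomic form factors: Cromer-Mann evaluation, the electron-withdrawing
# correction for water, and the uniform solvent-density correction.
#
# Entries are stored as (a, b, c) with a/b of arbitrary length so corrections
# that add Gaussians (the water correction) stay inside the representation.
# The species keys "OW"/"HW" denote oxygen/hydrogen belonging to a water
# molecule; only these ever receive water-specific corrections.

# Electron-withdrawing correction for water (Sorenson et al. parameters):
# f_HW'(q) = f_HW(q) - alpha * Z_H * g(q)
# f_OW'(q) = f_OW(q) + 2 * alpha * Z_H * g(q),   g(q) = exp(-q^2 / (2 delta^2))
# so the 10 electrons of a water molecule are conserved at q = 0 exactly.
.SWX_SORENSON_ALPHA <- 0.48
.SWX_SORENSON_DELTA <- 2.2  # 1/Angstrom

#' Load the bundled Cromer-Mann form-factor table
#'
#' Reads the neutral-atom 4-Gaussian coefficients shipped with the package and
#' adds water-species entries `OW`/`HW`: copies of O/H rescaled so that
#' f(0) equals the integer electron count exactly (a water molecule then
#' carries exactly 10 electrons, which the density-correction bookkeeping
#' relies on).
#'
#' @return A `swx_fftable`.
#' @export
load_form_factor_table <- function() {
  path <- system.file("extdata", "cromer_mann.tsv", package = "solvaxs")
  raw <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("element", paste0("a", 1:4),
                                  paste0("b", 1:4), "c", "Z"),
                    stringsAsFactors = FALSE)
  entries <- list()
  for (i in seq_len(nrow(raw))) {
    entries[[raw$element[i]]] <- list(
      a = as.numeric(raw[i, 2:5]),
      b = as.numeric(raw[i, 6:9]),
      c = raw$c[i],
      Z = raw$Z[i]
    )
  }
  rescale_to_Z <- function(e) {
    s <- e$Z / (sum(e$a) + e$c)
    list(a = e$a * s, b = e$b, c = e$c * s, Z = e$Z)
  }
  entries[["OW"]] <- rescale_to_Z(entries[["O"]])
  entries[["HW"]] <- rescale_to_Z(entries[["H"]])
  structure(list(entries = entries,
                 water_corrected = FALSE,
                 density_correction_e_per_water = 0),
            class = "swx_fftable")
}

#' @export
print.swx_fftable <- function(x, ...) {
  cat("<swx_fftable> ", length(x$entries), " entries; water correction ",
      if (x$water_corrected) "on" else "off",
      "; density correction ",
      format(x$density_correction_e_per_water, digits = 4),
      " e per water\n", sep = "")
  invisible(x)
}

#' Evaluate an atomic form factor
#'
#' Cromer-Mann evaluation `f(q) = sum_k a_k exp(-b_k (q/4pi)^2) + c` in
#' electrons, vectorized over `q`.
#'
#' @param table A `swx_fftable`.
#' @param element Table key (element symbol, or `OW`/`HW` for water atoms).
#' @param q Scattering-vector magnitudes in 1/Angstrom, all >= 0.
#' @return Numeric vector of form-factor values (electrons).
#' @export
form_factor <- function(table, element, q) {
  e <- table$entries[[element]]
  if (is.null(e)) stop("no form-factor entry for element '", element, "'")
  if (any(q < 0)) stop("q must be non-negative")
  s2 <- (q / (4 * pi))^2
  out <- rep(e$c, length(q))
  for (k in seq_along(e$a)) out <- out + e$a[k] * exp(-e$b[k] * s2)
  out
}

# f(q) for a vector of table keys at a single |q|; used in the hot path.
.swx_form_factors_at <- function(table, keys, q) {
  uk <- unique(keys)
  vals <- vapply(uk, function(k) form_factor(table, k, q), numeric(1))
  unname(vals[match(keys, uk)])
}

#' Apply the electron-withdrawing correction to water form factors
#'
#' Replaces the water-species entries (`OW`, `HW`) by corrected versions that
#' shift `alpha * Z_H` electrons per hydrogen into the oxygen with a Gaussian
#' q-profile (width `delta`), accounting for the polarization of the O-H
#' bond.  Non-water atoms are untouched and the 10 electrons per water
#' molecule are conserved at q = 0 by construction.
#'
#' @param table A `swx_fftable`.
#' @param enabled If `FALSE`, returns the table unchanged.
#' @param alpha Fraction of the hydrogen electron withdrawn at q = 0.
#' @param delta Gaussian width of the correction in 1/Angstrom.
#' @return The corrected `swx_fftable`.
#' @export
apply_water_correction <- function(table, enabled = TRUE,
                                   alpha = .SWX_SORENSON_ALPHA,
                                   delta = .SWX_SORENSON_DELTA) {
  if (!enabled || table$water_corrected) return(table)
  zh <- table$entries[["HW"]]$Z
  # g(q) = exp(-q^2/(2 delta^2)) as an extra Cromer-Mann Gaussian:
  # b_extra = (4 pi)^2 / (2 delta^2)
  b_extra <- (4 * pi)^2 / (2 * delta^2)
  ow <- table$entries[["OW"]]
  hw <- table$entries[["HW"]]
  ow$a <- c(ow$a, 2 * alpha * zh)
  ow$b <- c(ow$b, b_extra)
  hw$a <- c(hw$a, -alpha * zh)
  hw$b <- c(hw$b, b_extra)
  table$entries[["OW"]] <- ow
  table$entries[["HW"]] <- hw
  table$water_corrected <- TRUE
  table
}

#' Measure the bulk electron density of a water system
#'
#' Electrons (form-factor values at q = 0, so any density correction already
#' attached to the table is included) divided by the box volume, averaged
#' over frames.
#'
#' @param structure,trajectory The water system.
#' @param table A `swx_fftable`.
#' @return Density in e nm^-3.
#' @export
measure_bulk_density <- function(structure, trajectory, table) {
  box <- trajectory$box %||% structure$box
  if (is.null(box)) stop("water system has no box; cannot measure density")
  keys <- water_aware_keys(structure)
  electrons <- sum(.swx_form_factors_at(table, keys, 0))
  v_nm3 <- prod(box) / 1000  # A^3 -> nm^3
  electrons / v_nm3
}

#' Table keys for the atoms of a structure (water species aware)
#'
#' Atoms of water residues map to `OW`/`HW`; everything else maps to its
#' element symbol.
#'
#' @param structure A `swx_structure`.
#' @return Character vector of table keys, one per atom.
#' @export
water_aware_keys <- function(structure) {
  a <- structure$atoms
  keys <- a$element
  w <- .swx_is_water_resname(a$resname)
  keys[w & a$element == "O"] <- "OW"
  keys[w & a$element == "H"] <- "HW"
  keys
}

#' Apply the uniform solvent-density correction
#'
#' The computed curves are at small angles very sensitive to the solvent
#' density, and the density of the water model generally deviates from the
#' experimental buffer.  A small uniform electron density is therefore added
#' to the water (never fitted): the bulk density of the pure-water system is
#' measured, and `delta = (target - measured) * V_box / N_water` electrons per
#' water molecule are added to the constant term of the water-oxygen entry —
#' identically for the solute and pure-water systems, since both share the
#' table.
#'
#' @param table A `swx_fftable`.
#' @param water_structure,water_trajectory The pure-water system (must have a
#'   box).
#' @param target_density Target buffer density in e nm^-3 (334 corresponds to
#'   pure water).
#' @return The corrected `swx_fftable`.
#' @export
solvent_density_correction <- function(table, water_structure,
                                       water_trajectory,
                                       target_density = 334) {
  if (target_density <= 0) stop("target density must be positive")
  box <- water_trajectory$box %||% water_structure$box
  if (is.null(box)) stop("water system has no box")
  rho_sim <- measure_bulk_density(water_structure, water_trajectory, table)
  keys <- water_aware_keys(water_structure)
  n_water <- sum(keys == "OW")
  if (n_water == 0L) stop("no water molecules in the water system")
  v_nm3 <- prod(box) / 1000
  delta <- (target_density - rho_sim) * v_nm3 / n_water
  ow <- table$entries[["OW"]]
  ow$c <- ow$c + delta
  table$entries[["OW"]] <- ow
  table$density_correction_e_per_water <-
    table$density_correction_e_per_water + delta
  table
}
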