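# Brute-force Debye oracle: the exact closed form of the orientational
# average for point atoms.  Kept in plain R, independent of the quadrature
# path it validates.

#' Debye-formula intensity (validation oracle)
#'
#' `I(q) = sum_j sum_k f_j(q) f_k(q) sin(q r_jk) / (q r_jk)`, with the
#' `j = k` and `q -> 0` limits handled as 1.  Exact orientational average for
#' rigid point atoms; O(N^2) per q, intended for small systems as an
#' independent check of the spiral quadrature.
#'
#' @param coords n x 3 coordinate matrix (Angstrom), n up to ~1e3.
#' @param elements Table keys aligned with `coords`.
#' @param table A `swx_fftable`.
#' @param q Vector of q magnitudes (1/Angstrom).
#' @return Numeric intensities, one per q.
#' @export
debye_intensity <- function(coords, elements, table, q) {
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (n > 2000L) stop("debye_intensity is O(N^2); use < 2000 atoms")
  r <- as.matrix(stats::dist(coords))
  vapply(q, function(qi) {
    fv <- .swx_form_factors_at(table, elements, qi)
    x <- qi * r
    s <- ifelse(x == 0, 1, sin(x) / x)
    as.numeric(fv %*% s %*% fv)
  }, numeric(1))
}
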