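# Buffer-subtraction schemes, experimental-curve fitting (error-weighted and
# log-space metrics), Guinier analysis and q unit/convention conversion.

#' Convert scattering-vector values to the internal convention
#'
#' Internal units are 1/Angstrom in the q convention
#' (`q = 4 pi sin(theta) / lambda`).  Values in nm^-1 are divided by 10; the
#' s convention (`s = 2 sin(theta) / lambda`) is converted as `q = 2 pi s`.
#'
#' @param values Non-negative scattering-vector magnitudes.
#' @param from_units `"A^-1"` or `"nm^-1"`.
#' @param from_convention `"q"` or `"s"`.
#' @return Values in 1/Angstrom, q convention.
#' @export
convert_q <- function(values, from_units = c("A^-1", "nm^-1"),
                      from_convention = c("q", "s")) {
  from_units <- match.arg(from_units)
  from_convention <- match.arg(from_convention)
  if (any(values < 0)) stop("q values must be non-negative")
  out <- if (from_units == "nm^-1") values / 10 else values
  if (from_convention == "s") out <- 2 * pi * out
  out
}

.swx_exp_to_internal <- function(exp_curve) {
  q <- convert_q(exp_curve$q,
                 from_units = attr(exp_curve, "q_units") %||% "A^-1",
                 from_convention = attr(exp_curve, "convention") %||% "q")
  out <- tibble::tibble(q = q, I = exp_curve$I)
  if ("sigma" %in% names(exp_curve)) out$sigma <- exp_curve$sigma
  out
}

#' Apply a buffer-subtraction scheme
#'
#' The computed curve realizes the total scheme
#' `I = I_sam - I_buf`.  The reduced scheme
#' `I = I_sam - (1 - v) I_buf` additionally returns the solute volume
#' fraction `v` of the buffer intensity: `I_reduced = I_total + v * I_buf`.
#' `I_buf` here is the water scattering proper of the envelope volume, the
#' frame-fluctuation part `<|B|^2> - |<B>|^2` (non-negative by Jensen's
#' inequality): the coherent part `|<B>|^2` is the shape scattering of the
#' observation envelope, which a buffer measurement does not contain.  This
#' is an explicit approximation of the exact reduced-scheme correction
#' (flagged in the metadata).
#'
#' @param raw A `swx_curve` from [calc_intensity()] (total scheme); its
#'   metadata must carry `buffer_I` unless `buffer_intensity` is supplied.
#' @param scheme `"total"` or `"reduced"`.
#' @param v Solute volume fraction in `[0, 1)`; alternatively give
#'   `V_solute`.
#' @param V_solute Solute volume in Angstrom^3, converted to
#'   `v = V_solute / V_envelope` using the envelope volume in the metadata.
#' @param buffer_intensity Optional per-q buffer intensities overriding the
#'   metadata.
#' @return The subtracted `swx_curve` (metadata records scheme and v).
#' @export
apply_subtraction <- function(raw, scheme = c("total", "reduced"), v = NULL,
                              V_solute = NULL, buffer_intensity = NULL) {
  scheme <- match.arg(scheme)
  meta <- attr(raw, "meta") %||% list()
  if (scheme == "total") {
    meta$subtraction <- "total"
    attr(raw, "meta") <- meta
    return(raw)
  }
  buf <- buffer_intensity %||% meta$buffer_fluct
  if (is.null(buf)) stop("reduced scheme needs buffer intensities")
  if (length(buf) != nrow(raw)) stop("buffer intensity length mismatch")
  if (is.null(v)) {
    if (is.null(V_solute)) {
      stop("reduced scheme needs the volume fraction v or V_solute")
    }
    if (is.null(meta$envelope_volume)) {
      stop("V_solute given but the curve has no envelope volume metadata")
    }
    v <- V_solute / meta$envelope_volume
  }
  if (v < 0 || v >= 1) stop("volume fraction v must be in [0, 1)")
  out <- raw
  out$I <- raw$I + v * buf
  meta$subtraction <- "reduced (approximate v*I_buf correction)"
  meta$v <- v
  attr(out, "meta") <- meta
  out
}

# Interpolate the calculated curve onto the experimental grid; experimental
# points outside the calculated range are dropped, never extrapolated.
.swx_overlap <- function(calc, exp_int) {
  keep <- exp_int$q >= min(calc$q) & exp_int$q <= max(calc$q)
  exp_int <- exp_int[keep, , drop = FALSE]
  if (nrow(exp_int) < 3L) stop("fewer than 3 overlapping q points")
  Ic <- approx(calc$q, calc$I, xout = exp_int$q)$y
  list(q = exp_int$q, Icalc = Ic, Iexp = exp_int$I,
       sigma = if ("sigma" %in% names(exp_int)) exp_int$sigma)
}

.swx_fit_result <- function(f, c, ov, metric) {
  resid <- ov$Icalc - (f * ov$Iexp + c)
  chi2 <- if (!is.null(ov$sigma)) mean((resid / ov$sigma)^2) else NA_real_
  feas <- f * ov$Iexp + c
  chi2log <- if (all(ov$Icalc > 0) && all(feas > 0)) {
    mean((log(ov$Icalc) - log(feas))^2)
  } else {
    NA_real_
  }
  fitted <- new_curve(
    tibble::tibble(q = ov$q, I = f * ov$Iexp + c, I_calc = ov$Icalc),
    meta = list(f = f, c = c)
  )
  structure(list(f = f, c = c, chi2 = chi2, chi2log = chi2log,
                 chi = if (!is.na(chi2)) sqrt(chi2) else NA_real_,
                 chi_log = if (!is.na(chi2log)) sqrt(chi2log) else NA_real_,
                 n = length(ov$q), metric = metric, fitted_curve = fitted),
            class = "swx_fit")
}

#' @export
print.swx_fit <- function(x, ...) {
  cat(sprintf(
    "<swx_fit> metric %s: f = %.6g, c = %.6g (N = %d)\n", x$metric, x$f, x$c,
    x$n))
  cat(sprintf("  chi^2 = %s (chi = %s), chi^2_log = %s (chi_log = %s)\n",
              format(x$chi2, digits = 6), format(x$chi, digits = 6),
              format(x$chi2log, digits = 6), format(x$chi_log, digits = 6)))
  invisible(x)
}

#' Fit an experimental curve with the error-weighted metric
#'
#' Minimizes `chi^2(f, c) = N^-1 sum [(I_calc - (f I_exp + c)) / sigma]^2`
#' over scale `f` and offset `c`.  The experimental curve is transformed to
#' match the calculated one (never the reverse): the calculated curve
#' contains no free parameters.  The minimizer is the closed-form solution of
#' the 2 x 2 weighted normal equations.
#'
#' @param calc The calculated `swx_curve`.
#' @param exp_curve The experimental curve (see [read_curve()]); must carry
#'   errors `sigma`, otherwise the fit falls back to [fit_chi2log()] with a
#'   warning.
#' @return A `swx_fit`: scale `f`, offset `c`, both metric values at the
#'   optimum, and the transformed experimental curve.
#' @export
fit_chi2 <- function(calc, exp_curve) {
  ov <- .swx_overlap(calc, .swx_exp_to_internal(exp_curve))
  if (is.null(ov$sigma)) {
    warning("experimental curve has no errors; falling back to the ",
            "log-space metric")
    return(fit_chi2log(calc, exp_curve))
  }
  w <- 1 / ov$sigma^2
  sw <- sum(w)
  mx <- sum(w * ov$Iexp) / sw
  my <- sum(w * ov$Icalc) / sw
  sxx <- sum(w * (ov$Iexp - mx)^2)
  sxy <- sum(w * (ov$Iexp - mx) * (ov$Icalc - my))
  if (sxx == 0) stop("experimental intensities are constant; cannot fit f")
  f <- sxy / sxx
  c <- my - f * mx
  .swx_fit_result(f, c, ov, metric = "chi2")
}

#' Fit an experimental curve with the log-space metric
#'
#' Minimizes `chi2_log(f, c) = N^-1 sum [log I_calc - log(f I_exp + c)]^2`,
#' which weights small and wide angles more uniformly than the error-weighted
#' metric and suits wide-angle data.  Deterministic two-stage minimization:
#' a coarse logarithmic grid over `f` with the optimal `c` from a
#' one-dimensional search, then a derivative-free polish; the feasibility
#' constraint `f I_exp + c > 0` is enforced throughout.
#'
#' @inheritParams fit_chi2
#' @return A `swx_fit`.
#' @export
fit_chi2log <- function(calc, exp_curve) {
  ov <- .swx_overlap(calc, .swx_exp_to_internal(exp_curve))
  if (any(ov$Icalc <= 0)) {
    stop("calculated intensities must be positive for the log metric")
  }
  lc <- log(ov$Icalc)
  obj_c <- function(f) {
    # best c for fixed f by golden-section on the feasible interval
    lo <- -f * min(ov$Iexp) # feasibility boundary: f*Iexp + c > 0
    scale <- max(abs(ov$Icalc), abs(f * ov$Iexp))
    fn <- function(c) {
      y <- f * ov$Iexp + c
      if (any(y <= 0)) return(Inf)
      mean((lc - log(y))^2)
    }
    opt <- optimize(fn, interval = c(lo + 1e-12 * scale, lo + 10 * scale))
    list(c = opt$minimum, value = opt$objective)
  }
  # coarse log grid over f around the scale ratio of the two curves
  f0 <- stats::median(ov$Icalc) / max(stats::median(ov$Iexp), 1e-300)
  if (!is.finite(f0) || f0 <= 0) f0 <- 1
  fgrid <- f0 * 10^seq(-2, 2, length.out = 41)
  vals <- vapply(fgrid, function(f) obj_c(f)$value, numeric(1))
  fbest <- fgrid[which.min(vals)]
  cbest <- obj_c(fbest)$c
  # derivative-free polish in (log f, c)
  pol <- optim(c(log(fbest), cbest), function(p) {
    f <- exp(p[1])
    y <- f * ov$Iexp + p[2]
    if (any(y <= 0)) return(.Machine$double.xmax)
    mean((lc - log(y))^2)
  }, method = "Nelder-Mead",
  control = list(reltol = 1e-14, maxit = 5000))
  .swx_fit_result(exp(pol$par[1]), pol$par[2], ov, metric = "chi2log")
}

#' Guinier analysis of a scattering curve
#'
#' Straight-line fit of `ln I` against `q^2` on the low-q window, yielding
#' the zero-angle intensity `I0 = exp(intercept)` and the radius of gyration
#' `Rg = sqrt(-3 * slope)`.  The window is chosen by the community-standard
#' smallness criterion `q * Rg <= qrg_max`, iterated to self-consistency from
#' an initial window of the lowest 20% of points.
#'
#' @param curve A `swx_curve` (or data frame with `q`, `I`).
#' @param qrg_max Upper bound on `q * Rg` for points entering the fit
#'   (default 1.3).
#' @param min_points Minimum number of points in the window (default 5).
#' @return A `swx_guinier`: list with `I0`, `Rg` (Angstrom), `q_range_used`,
#'   `n_points`.
#' @export
guinier_fit <- function(curve, qrg_max = 1.3, min_points = 5) {
  ok <- is.finite(curve$q) & is.finite(curve$I) & curve$I > 0
  qv <- curve$q[ok]; Iv <- curve$I[ok]
  if (length(qv) < min_points) {
    stop("too few positive points for a Guinier fit")
  }
  idx <- seq_len(max(min_points, ceiling(0.2 * length(qv))))
  rg_from <- function(idx) {
    fit <- lm(lnI ~ q2, data = data.frame(lnI = log(Iv[idx]),
                                          q2 = qv[idx]^2))
    slope <- coef(fit)[[2]]
    if (slope >= 0) {
      stop("non-physical Guinier region (ln I does not decrease with q^2)")
    }
    list(Rg = sqrt(-3 * slope), I0 = exp(coef(fit)[[1]]))
  }
  res <- rg_from(idx)
  for (iter in seq_len(25)) {
    new_idx <- which(qv * res$Rg <= qrg_max)
    if (length(new_idx) < min_points) new_idx <- seq_len(min_points)
    if (identical(new_idx, idx)) break
    idx <- new_idx
    res <- rg_from(idx)
  }
  structure(list(I0 = res$I0, Rg = res$Rg,
                 q_range_used = range(qv[idx]), n_points = length(idx),
                 qrg_max = qrg_max),
            class = "swx_guinier")
}

#' @export
print.swx_guinier <- function(x, ...) {
  cat(sprintf(
    "<swx_guinier> Rg = %.3f A, I0 = %.6g (%d points, q in [%.4g, %.4g])\n",
    x$Rg, x$I0, x$n_points, x$q_range_used[1], x$q_range_used[2]))
  invisible(x)
}
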