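# ggplot2 display methods and broom-style accessors for result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   scale_y_log10 labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a scattering curve
#'
#' Log-intensity versus q, with a statistical-error ribbon when available.
#'
#' @param object A `swx_curve`.
#' @param log_y Use a logarithmic intensity axis (default TRUE; requires
#'   positive intensities).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot swx_curve
#' @export
autoplot.swx_curve <- function(object, log_y = TRUE, ...) {
  df <- as.data.frame(object)
  p <- ggplot(df, aes(x = q, y = I))
  if ("sigma" %in% names(df) && any(df$sigma > 0)) {
    p <- p + geom_ribbon(aes(ymin = I - sigma, ymax = I + sigma),
                         alpha = 0.25)
  }
  p <- p + geom_line() +
    labs(x = expression(q ~ (ring(A)^-1)), y = "I(q)") +
    theme_minimal()
  if (log_y && all(df$I > 0)) p <- p + scale_y_log10()
  p
}

#' Plot a fit of an experimental curve
#'
#' The calculated curve with the transformed experimental points
#' `f I_exp + c` overlaid.
#'
#' @param object A `swx_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot swx_fit
#' @export
autoplot.swx_fit <- function(object, ...) {
  df <- as.data.frame(object$fitted_curve)
  p <- ggplot(df, aes(x = q)) +
    geom_line(aes(y = I_calc)) +
    geom_point(aes(y = I), size = 0.8, colour = "red") +
    labs(x = expression(q ~ (ring(A)^-1)), y = "I(q)",
         title = sprintf("fit (%s): f = %.4g, c = %.4g",
                         object$metric, object$f, object$c)) +
    theme_minimal()
  if (all(df$I_calc > 0) && all(df$I > 0)) p <- p + scale_y_log10()
  p
}

#' Tidy a curve fit
#' @param x A `swx_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter.
#' @method tidy swx_fit
#' @export
tidy.swx_fit <- function(x, ...) {
  tibble::tibble(term = c("f", "c"), estimate = c(x$f, x$c))
}

#' One-row fit summary
#' @param x A `swx_fit`.
#' @param ... Unused.
#' @return A tibble with the metric values and point count.
#' @method glance swx_fit
#' @export
glance.swx_fit <- function(x, ...) {
  tibble::tibble(metric = x$metric, chi2 = x$chi2, chi = x$chi,
                 chi2log = x$chi2log, chi_log = x$chi_log, n = x$n)
}

#' Tidy a Guinier fit
#' @param x A `swx_guinier`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`Rg`, `I0`).
#' @method tidy swx_guinier
#' @export
tidy.swx_guinier <- function(x, ...) {
  tibble::tibble(term = c("Rg", "I0"), estimate = c(x$Rg, x$I0))
}

#' One-row Guinier summary
#' @param x A `swx_guinier`.
#' @param ... Unused.
#' @return A tibble with `Rg`, `I0`, the window and point count.
#' @method glance swx_guinier
#' @export
glance.swx_guinier <- function(x, ...) {
  tibble::tibble(Rg = x$Rg, I0 = x$I0, q_min = x$q_range_used[1],
                 q_max = x$q_range_used[2], n_points = x$n_points)
}
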