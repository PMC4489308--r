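# Buffer-subtraction schemes, fitting metrics, Guinier analysis, unit
# conversion.

make_exp_curve <- function(q, I, sigma = NULL, q_units = "A^-1",
                           convention = "q") {
  df <- tibble::tibble(q = q, I = I)
  if (!is.null(sigma)) df$sigma <- sigma
  new_curve(df, q_units = q_units, convention = convention)
}

test_that("q conversion follows the two printed definitions", {
  expect_equal(convert_q(1, "nm^-1", "q"), 0.1)
  expect_equal(convert_q(0.1, "A^-1", "s"), 0.2 * pi)  # q = 2 pi s
  expect_equal(convert_q(0.1, "A^-1", "s"), 0.6283, tolerance = 1e-4)
  # round trip is the identity
  q <- seq(0, 2, by = 0.1)
  expect_equal(convert_q(q * 10, "nm^-1", "q"), q, tolerance = 1e-12)
  expect_equal(convert_q(q / (2 * pi), "A^-1", "s"), q, tolerance = 1e-12)
  expect_error(convert_q(-1), "non-negative")
})

test_that("subtraction schemes differ by v * I_buf and agree at v = 0", {
  fx <- solvated_fixture()
  q <- qgrid(1, 21)
  raw <- calc_intensity(fx$pair$solute, fx$pair$water, envelope = fx$env,
                        q = q, table = fx$tab)
  tot <- apply_subtraction(raw, "total")
  expect_equal(tot$I, raw$I)
  red0 <- apply_subtraction(raw, "reduced", v = 0)
  expect_equal(red0$I, tot$I)
  v <- 0.03
  red <- apply_subtraction(raw, "reduced", v = v)
  buf <- attr(raw, "meta")$buffer_fluct
  expect_equal(red$I - tot$I, v * buf, tolerance = 1e-12)
  expect_true(all(red$I - tot$I >= 0))
  # water scattering gains weight toward wide angles
  ratio <- (red$I - tot$I) / tot$I
  expect_gt(ratio[length(q)], ratio[2])
  # v from a solute volume and the envelope volume
  meta <- attr(raw, "meta")
  redv <- apply_subtraction(raw, "reduced", V_solute = 905)
  expect_equal(attr(redv, "meta")$v, 905 / meta$envelope_volume)
  expect_error(apply_subtraction(raw, "reduced"), "v or V_solute")
  expect_error(apply_subtraction(raw, "reduced", v = 1.2), "\\[0, 1\\)")
})

test_that("the error-weighted fit recovers planted parameters exactly", {
  q <- seq(0.01, 0.5, by = 0.01)
  Ic <- 1e4 * exp(-q^2 * 70) + 50
  calc <- make_exp_curve(q, Ic)
  f0 <- 2.5; c0 <- -120
  expc <- make_exp_curve(q, (Ic - c0) / f0, sigma = 0.5 + q)
  fit <- fit_chi2(calc, expc)
  expect_equal(fit$f, f0, tolerance = 1e-10)
  expect_equal(fit$c, c0, tolerance = 1e-8)
  expect_lt(fit$chi2, 1e-10)
  expect_equal(fit$fitted_curve$I, Ic, tolerance = 1e-8)
  # scaling all sigmas leaves (f, c) unchanged and divides chi2 by s^2
  noisy <- make_exp_curve(q, (Ic - c0) / f0 * (1 + 0.05 * sin(37 * q)),
                          sigma = 0.5 + q)
  fitn <- fit_chi2(calc, noisy)
  noisy2 <- noisy
  noisy2$sigma <- noisy$sigma * 3
  fitn2 <- fit_chi2(calc, noisy2)
  expect_equal(fitn2$f, fitn$f, tolerance = 1e-12)
  expect_equal(fitn2$c, fitn$c, tolerance = 1e-9)
  expect_equal(fitn2$chi2, fitn$chi2 / 9, tolerance = 1e-9)
})

test_that("the closed-form minimizer beats a brute-force grid", {
  q <- seq(0.01, 0.5, by = 0.01)
  Ic <- 1e4 * exp(-q^2 * 70) + 50
  calc <- make_exp_curve(q, Ic)
  expc <- make_exp_curve(q, Ic / 2 * (1 + 0.08 * cos(23 * q)) + 30,
                         sigma = 1 + 10 * q)
  fit <- fit_chi2(calc, expc)
  # grid around the optimum: no grid point does better
  fs <- seq(fit$f * 0.9, fit$f * 1.1, length.out = 200)
  cs <- seq(fit$c - abs(fit$c) - 10, fit$c + abs(fit$c) + 10,
            length.out = 200)
  chi2 <- function(f, c) {
    mean(((Ic - (f * expc$I + c)) / expc$sigma)^2)
  }
  grid_best <- min(vapply(fs, function(f) {
    min(vapply(cs, function(c) chi2(f, c), numeric(1)))
  }, numeric(1)))
  expect_lte(fit$chi2, grid_best + 1e-12)
  # perturbing the optimum never helps
  for (df in c(-0.01, 0.01)) {
    expect_gte(chi2(fit$f * (1 + df), fit$c), fit$chi2)
    expect_gte(chi2(fit$f, fit$c + df * max(abs(fit$c), 1)), fit$chi2)
  }
})

test_that("the log-space fit recovers planted parameters and scales", {
  q <- seq(0.01, 0.5, by = 0.01)
  Ic <- 1e4 * exp(-q^2 * 70) + 50
  calc <- make_exp_curve(q, Ic)
  f0 <- 0.8; c0 <- 15
  expc <- make_exp_curve(q, (Ic - c0) / f0)
  fit <- fit_chi2log(calc, expc)
  expect_equal(fit$f, f0, tolerance = 1e-6)
  expect_equal(fit$c, c0, tolerance = 1e-4)
  expect_lt(fit$chi2log, 1e-10)
  # scaling the calculated curve scales f and c, chi2log unchanged
  s <- 7
  calc_s <- make_exp_curve(q, Ic * s)
  noisy <- make_exp_curve(q, (Ic - c0) / f0 * (1 + 0.05 * sin(37 * q)))
  fit1 <- fit_chi2log(calc, noisy)
  fit2 <- fit_chi2log(calc_s, noisy)
  expect_equal(fit2$f / fit1$f, s, tolerance = 1e-3)
  expect_equal(fit2$c / fit1$c, s, tolerance = 1e-2)
  expect_equal(fit2$chi2log, fit1$chi2log, tolerance = 1e-6)
  # matches a brute-force grid refine
  fitn <- fit_chi2log(calc, noisy)
  fs <- exp(seq(log(fitn$f) - 0.1, log(fitn$f) + 0.1, length.out = 120))
  cs <- seq(fitn$c - 30, fitn$c + 30, length.out = 120)
  obj <- function(f, c) {
    y <- f * noisy$I + c
    if (any(y <= 0)) return(Inf)
    mean((log(Ic) - log(y))^2)
  }
  grid_best <- min(vapply(fs, function(f) {
    min(vapply(cs, function(c) obj(f, c), numeric(1)))
  }, numeric(1)))
  expect_lte(fitn$chi2log, grid_best + 1e-10)
})

test_that("fits are invariant under point reordering and need overlap", {
  q <- seq(0.01, 0.3, by = 0.01)
  Ic <- 1000 * exp(-q^2 * 50) + 10
  calc <- make_exp_curve(q, Ic)
  expc <- make_exp_curve(q, Ic / 3 + 5, sigma = rep(1, length(q)))
  f1 <- fit_chi2(calc, expc)
  # permuting the experimental points changes nothing
  perm <- sample(seq_along(q))
  expc_perm <- make_exp_curve(q[perm], (Ic / 3 + 5)[perm],
                              sigma = rep(1, length(q)))
  f2 <- fit_chi2(calc, expc_perm)
  expect_equal(f2$f, f1$f, tolerance = 1e-12)
  expect_equal(f2$chi2, f1$chi2, tolerance = 1e-12)
  f1l <- fit_chi2log(calc, expc)
  f2l <- fit_chi2log(calc, expc_perm)
  expect_equal(f2l$f, f1l$f, tolerance = 1e-6)
  # missing sigma falls back to the log metric with a warning
  expc_nosigma <- make_exp_curve(q, Ic / 3 + 5)
  expect_warning(fb <- fit_chi2(calc, expc_nosigma), "falling back")
  expect_equal(fb$metric, "chi2log")
  # fewer than 3 overlapping points is an error
  short <- make_exp_curve(c(0.6, 0.7, 0.8), c(1, 1, 1),
                          sigma = c(1, 1, 1))
  expect_error(fit_chi2(calc, short), "overlapping")
})

test_that("experimental units and conventions are resolved at fit time", {
  q <- seq(0.01, 0.3, by = 0.01)
  Ic <- 1000 * exp(-q^2 * 50) + 10
  calc <- make_exp_curve(q, Ic)
  # the same data declared in nm^-1: q column times 10
  expc_nm <- make_exp_curve(q * 10, Ic / 2, sigma = rep(1, length(q)),
                            q_units = "nm^-1")
  fit <- fit_chi2(calc, expc_nm)
  expect_equal(fit$f, 2, tolerance = 1e-9)
  expect_lt(fit$chi2, 1e-18)
})

test_that("Guinier fit is exact on a Gaussian and biased down by offsets", {
  Rg <- 15
  q <- seq(0.001, 0.12, by = 0.002)
  I0 <- 5e4
  cur <- make_exp_curve(q, I0 * exp(-q^2 * Rg^2 / 3))
  g <- guinier_fit(cur)
  expect_equal(g$Rg, 15, tolerance = 1e-6)
  expect_equal(g$I0, I0, tolerance = 1e-4)
  # window criterion: every used point satisfies q * Rg <= 1.3
  expect_lte(g$q_range_used[2] * g$Rg, 1.3 + 1e-9)
  # constant positive offsets bias Rg downward, monotonically
  rgs <- vapply(c(0, 0.01, 0.05), function(off) {
    guinier_fit(make_exp_curve(q, I0 * (exp(-q^2 * Rg^2 / 3) + off)))$Rg
  }, numeric(1))
  expect_true(all(diff(rgs) < 0))
  # a rising curve has no Guinier region
  expect_error(guinier_fit(make_exp_curve(q, exp(q^2 * 100))),
               "non-physical")
  expect_error(guinier_fit(make_exp_curve(q[1:4], rep(1, 4))), "too few")
})
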