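# Quadrature rule, spiral points, amplitudes, three-term intensity, and the
# Debye oracle.

test_that("J_q rule has the stated floor, branch and monotonicity", {
  expect_equal(jq_count(0, 50), 100L)
  expect_equal(jq_count(1, 100), 2000L)     # qD = 100 -> 0.2 * 1e4
  expect_equal(jq_count(0.1, 10), 100L)     # small qD stays on the floor
  qs <- seq(0, 2, by = 0.05)
  expect_true(all(diff(jq_count(qs, 80)) >= 0))
  expect_error(jq_count(-0.1, 10), "non-negative")
  expect_error(jq_count(0.1, 0), "positive")
})

test_that("spiral directions are unit, balanced and near-uniform", {
  expect_equal(sqrt(sum(spiral_directions(1)^2)), 1, tolerance = 1e-12)
  s100 <- spiral_directions(100)
  expect_lt(max(abs(sqrt(rowSums(s100^2)) - 1)), 1e-12)
  expect_lt(sqrt(sum(colMeans(s100)^2)), 0.05)
  # nearest-neighbor angles within a factor 2 of the ideal sqrt(4 pi / J)
  s <- spiral_directions(1000)
  dots <- s %*% t(s)
  diag(dots) <- -2
  nn <- acos(pmin(1, apply(dots, 1, max)))
  ideal <- sqrt(4 * pi / 1000)
  expect_gt(min(nn), ideal / 2)
  expect_lt(max(nn), ideal * 2)
  expect_error(spiral_directions(0), ">= 1")
})

test_that("amplitudes obey zero-phase, single-atom and shift properties", {
  tab <- load_form_factor_table()
  xyz <- ball_points(8, 4, seed = 6)
  els <- rep(c("C", "N"), 4)
  a0 <- amplitude(xyz, els, tab, c(0, 0, 0))
  expect_equal(Im(a0), 0, tolerance = 1e-12)
  expect_equal(Re(a0), sum(vapply(els, function(e) form_factor(tab, e, 0),
                                  numeric(1))), tolerance = 1e-9)
  # single atom at the origin: f(|q|) along any direction
  qv <- rbind(c(0.3, 0, 0), c(0, 0.3, 0), c(0.1, 0.2, sqrt(0.04)))
  a1 <- amplitude(matrix(0, 1, 3), "C", tab, qv)
  expect_equal(Re(a1), rep(form_factor(tab, "C", 0.3), 3), tolerance = 1e-9)
  expect_equal(Im(a1), rep(0, 3), tolerance = 1e-12)
  # rigid translation only changes the phase, never the modulus
  qvec <- c(0.4, -0.2, 0.1)
  b1 <- amplitude(xyz, els, tab, qvec)
  b2 <- amplitude(sweep(xyz, 2, c(3.3, -1.1, 2.2), "+"), els, tab, qvec)
  expect_equal(Mod(b1), Mod(b2), tolerance = 1e-10)
  phase <- exp(-1i * sum(qvec * c(3.3, -1.1, 2.2)))
  expect_equal(b2, b1 * phase, tolerance = 1e-10)
})

test_that("Debye oracle matches closed forms and MC quadrature", {
  tab <- load_form_factor_table()
  # two identical atoms at distance r
  r <- 4.2
  q <- c(0.2, 0.7)
  fC <- form_factor(tab, "C", q)
  expected <- 2 * fC^2 * (1 + sin(q * r) / (q * r))
  got <- debye_intensity(rbind(c(0, 0, 0), c(r, 0, 0)), c("C", "C"), tab, q)
  expect_equal(got, expected, tolerance = 1e-12)
  # q = 0 limit: (sum of f(0))^2
  xyz <- ball_points(10, 2, seed = 2)
  els <- rep("O", 10)
  expect_equal(debye_intensity(xyz, els, tab, 0),
               sum(form_factor(tab, "O", 0) * rep(1, 10))^2,
               tolerance = 1e-9)
  # dense random-direction quadrature agrees to 0.1%
  qq <- c(0.1, 0.2, 0.3)
  mc <- mc_orientational_intensity(xyz, els, tab, qq, n = 1e4)
  dd <- debye_intensity(xyz, els, tab, qq)
  expect_rel(mc, dd, 1e-3)
})

test_that("vacuum intensity of a single carbon equals f_C(q)^2", {
  tab <- load_form_factor_table()
  sys <- vacuum_system(matrix(c(1, 2, 3), 1, 3))
  q <- qgrid(1, 11)
  cv <- calc_intensity(sys, q = q, table = tab)
  expect_equal(cv$I, form_factor(tab, "C", q)^2, tolerance = 1e-9)
})

test_that("identical solute and water systems cancel exactly", {
  fx <- solvated_fixture()
  q <- qgrid(1, 11)
  cv <- calc_intensity(fx$pair$water, fx$pair$water, envelope = fx$env,
                       q = q, table = fx$tab)
  buf <- attr(cv, "meta")$buffer_I
  expect_true(all(abs(cv$I) <= 1e-9 * buf))
})

test_that("spiral average converges to the Debye oracle for rigid atoms", {
  tab <- load_form_factor_table()
  xyz <- ball_points(20, 6, seed = 1)
  els <- rep("C", 20)
  q <- qgrid(1, 26)
  oracle <- debye_intensity(xyz, els, tab, q)
  sys <- vacuum_system(xyz)
  got <- calc_intensity(sys, q = q, table = tab)
  expect_rel(got$I, oracle, 5e-3)
  # error shrinks monotonically in expectation as J grows
  errs <- vapply(c(1, 4, 16), function(m) {
    max(abs(calc_intensity(sys, q = q, table = tab,
                           jq_multiplier = m)$I - oracle) / oracle)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("quadrature is converged at the J_q rule on the vacuum fixture", {
  tab <- load_form_factor_table()
  sys <- vacuum_system(ball_points(20, 6, seed = 1))
  q <- qgrid(1, 26)
  i1 <- calc_intensity(sys, q = q, table = tab)$I
  i2 <- calc_intensity(sys, q = q, table = tab, jq_multiplier = 2)$I
  expect_lt(max(abs(i2 - i1) / i1), 5e-3)
})

test_that("intensity is invariant under rigid rotation of the system", {
  tab <- load_form_factor_table()
  xyz <- ball_points(20, 6, seed = 1)
  q <- qgrid(1, 6)
  i1 <- calc_intensity(vacuum_system(xyz), q = q, table = tab)$I
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  i2 <- calc_intensity(vacuum_system(xyz %*% rot), q = q, table = tab)$I
  expect_rel(i2, i1, 1e-2)
})

test_that("frame averages satisfy the Jensen inequality per direction", {
  fx <- solvated_fixture()
  cv <- calc_intensity(fx$pair$solute, fx$pair$water, envelope = fx$env,
                       q = c(0, 0.3, 0.8), table = fx$tab,
                       keep_components = TRUE)
  for (comp in attr(cv, "meta")$components) {
    expect_true(all(Mod(comp$meanA)^2 <= comp$meanA2 * (1 + 1e-12) + 1e-9))
    expect_true(all(Mod(comp$meanB)^2 <= comp$meanB2 * (1 + 1e-12) + 1e-9))
  }
})

test_that("intensity preconditions are enforced", {
  fx <- solvated_fixture()
  # envelope larger than the water box
  big_env <- build_envelope(matrix(c(18, 18, 18), 1, 3), d = 25, depth = 1)
  expect_error(
    calc_intensity(fx$pair$solute, fx$pair$water, envelope = big_env,
                   q = c(0, 0.1), table = fx$tab),
    "does not fit")
  # buffer subtraction needs an envelope and >= 2 frames
  expect_error(
    calc_intensity(fx$pair$solute, fx$pair$water, envelope = NULL,
                   q = c(0, 0.1), table = fx$tab),
    "envelope")
  one_frame <- fx$pair$solute
  one_frame$trajectory <- new_trajectory(one_frame$trajectory$coords[1],
                                         times = 0,
                                         box = one_frame$trajectory$box)
  expect_error(
    calc_intensity(one_frame, fx$pair$water, envelope = fx$env,
                   q = c(0, 0.1), table = fx$tab),
    ">= 2 frames")
})
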