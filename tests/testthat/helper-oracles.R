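# Independent oracles used only by the tests.

# Ray-casting parity oracle for point-in-mesh: casts a ray from each point in
# a fixed direction and counts Moller-Trumbore triangle intersections on the
# explicit envelope mesh; odd parity = inside.  Independent of the package's
# barycentric-radius containment test.
raycast_inside <- function(envelope, points, dir = c(0.12345, 0.54321,
                                                     0.82163)) {
  dir <- dir / sqrt(sum(dir^2))
  verts <- sweep(envelope$directions * envelope$radii, 2,
                 envelope$center, "+")
  f <- envelope$faces
  v0 <- verts[f[, 1], , drop = FALSE]
  e1 <- verts[f[, 2], , drop = FALSE] - v0
  e2 <- verts[f[, 3], , drop = FALSE] - v0
  # h = dir x e2 (constant dir)
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  inv_a <- ifelse(ok, 1 / a, NA_real_)
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  vapply(seq_len(nrow(points)), function(i) {
    s <- sweep(v0, 2, points[i, ], "-") * -1
    u <- rowSums(s * h) * inv_a
    qv <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
                s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
                s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
    v <- (qv %*% dir) * inv_a
    t <- rowSums(qv * e2) * inv_a
    hits <- ok & u >= 0 & u <= 1 & v >= 0 & (u + v) <= 1 & t > 1e-9
    sum(hits, na.rm = TRUE) %% 2 == 1
  }, logical(1))
}

# dense Monte-Carlo orientational average of |A(q)|^2 (random directions)
mc_orientational_intensity <- function(coords, elements, table, q, n = 1e4,
                                       seed = 3) {
  solvaxs:::.swx_with_seed(seed, {
    dirs <- matrix(rnorm(3 * n), n, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    vapply(q, function(qi) {
      a <- amplitude(coords, elements, table, dirs * qi)
      mean(Re(a * Conj(a)))
    }, numeric(1))
  })
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
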