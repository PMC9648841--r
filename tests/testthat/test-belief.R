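test_that("belief grids have the lattice point count and valid points", {
  expect_equal(nrow(make_grid(1)$points), 3)
  expect_equal(nrow(make_grid(0.5)$points), 6)
  g <- make_grid(0.02)
  M <- 50
  expect_equal(nrow(g$points), (M + 1) * (M + 2) / 2)   # 1326
  expect_equal(rowSums(g$points), rep(1, nrow(g$points)))
  expect_true(all(g$points >= 0))
  # the three vertices are grid points
  for (v in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
    expect_true(any(apply(g$points, 1, function(x) all(x == v))))
  expect_error(make_grid(0.3), "integer")
})

test_that("barycentric interpolation is exact, convex, and affine-reproducing", {
  g <- make_grid(0.1)
  vals <- stats::runif(nrow(g$points))
  # exact at grid points
  expect_equal(interpolate_grid(g, vals, g$points), vals)
  # constant tables stay constant
  set.seed(1)
  B <- t(replicate(200, { x <- stats::rexp(3); x / sum(x) }))
  expect_equal(interpolate_grid(g, rep(2.5, nrow(g$points)), B),
               rep(2.5, 200))
  # affine functions of the belief reproduce exactly
  expect_equal(interpolate_grid(g, g$points[, 2], B), B[, 2], tolerance = 1e-12)
  # convex combination of corner values
  expect_true(all(interpolate_grid(g, vals, B) <= max(vals) + 1e-12))
  expect_true(all(interpolate_grid(g, vals, B) >= min(vals) - 1e-12))
})

test_that("belief updates follow Bayes with transition after likelihood", {
  p <- task_params()
  # certainty in pre is preserved before the arrival window
  for (o in c(-1, 0, 2)) for (n in 1:(p$N0 - 1))
    expect_equal(belief_update(c(1, 0, 0), "weak", o, n, p)$belief, c(1, 0, 0))
  # normalization
  up <- belief_update(c(0.2, 0.5, 0.3), "strong", 0.7, 6, p)
  expect_equal(sum(up$belief), 1)
  # oracle: direct evaluation of the filter at b = (.5,.5,0), o = 1, n = 5
  lik <- stats::dnorm(1, c(0, 1, 0), p$sigma_s)
  v <- c(0.5, 0.5, 0) * lik
  Tn <- rbind(c(0.9, 0.1, 0), c(0, 0.8, 0.2), c(0, 0, 1))  # hazard(6) = 0.1
  expected <- as.numeric(v %*% Tn) / sum(v)
  got <- belief_update(c(0.5, 0.5, 0), "strong", 1, 5, p)
  expect_equal(got$belief, expected, tolerance = 1e-12)
  expect_equal(got$evidence, sum(v), tolerance = 1e-12)
  expect_gt(got$belief[2] + got$belief[3], 0.5)
})

test_that("evidence integrates to one over observations", {
  p <- task_params()
  o <- seq(-8, 9, length.out = 4001)
  h <- o[2] - o[1]
  for (a in c("weak", "strong")) {
    b <- c(0.3, 0.45, 0.25)
    ev <- vapply(o, function(oo) belief_update(b, a, oo, 5, p)$evidence,
                 numeric(1))
    expect_equal(sum(ev) * h, 1, tolerance = 1e-6)
  }
})

test_that("with near-uninformative observations filtering reduces to propagation", {
  p <- task_params(sigma_w = 50, sigma_s = 50)
  b <- c(1, 0, 0)
  prior <- c(1, 0, 0)
  set.seed(3)
  for (n in 1:8) {
    b <- belief_update(b, "weak", stats::rnorm(1, 0, 50), n, p)$belief
    prior <- as.numeric(prior %*% external_transition(n, p))
  }
  expect_equal(b, prior, tolerance = 0.02)
})

test_that("discretized belief transitions are stochastic and martingale", {
  p <- task_params()
  g <- make_grid(0.05)
  quad <- make_quadrature(p, 201)
  Phi <- belief_transition_matrix(5, "strong", g, p, quad)
  expect_equal(as.numeric(Matrix::rowSums(Phi)), rep(1, nrow(g$points)),
               tolerance = 1e-12)
  # expected successor belief equals prior propagation (the scatter is
  # mean-preserving and the quadrature is dense)
  Tn <- external_transition(5, p)
  expected <- g$points %*% Tn
  got <- as.matrix(Phi %*% g$points)
  expect_equal(unname(got), unname(expected), tolerance = 1e-4)
  # identical likelihoods give identical operators for the two actions
  peq <- task_params(sigma_s = 1, sigma_w = 1)
  qeq <- make_quadrature(peq, 101)
  Pw <- belief_transition_matrix(5, "weak", g, peq, qeq)
  Ps <- belief_transition_matrix(5, "strong", g, peq, qeq)
  expect_lt(max(abs(Pw - Ps)), 1e-12)
  expect_error(belief_transition_matrix(5, "weak", g, p, list(nodes = numeric(0))),
               "quadrature")
})

test_that("belief rewards combine attentional cost and expected report reward", {
  p <- task_params()
  expect_equal(belief_reward(c(0.2, 0.3, 0.5), "weak", "weak", 4, p), 0)
  expect_equal(belief_reward(c(1, 0, 0), "weak", "weak", p$N, p,
                             report = "no_signal"), 1)
  expect_equal(belief_reward(c(0.7, 0.1, 0.2), "weak", "weak", p$N, p,
                             report = "no_signal"), 0.7)
  expect_equal(belief_reward(c(0.7, 0.1, 0.2), "weak", "weak", p$N, p,
                             report = "signal"), 0.3)
  expect_equal(belief_reward(c(0.7, 0.1, 0.2), "strong", "strong", p$N, p,
                             report = "signal"), 0.3 + p$epsilon)
  expect_error(belief_reward(c(1, 0, 0), "weak", "weak", p$N, p), "report")
})

test_that("nearest grid point returns the dominant triangle corner", {
  g <- make_grid(0.1)
  id <- nearest_grid_point(g, c(0.52, 0.48, 0))
  expect_equal(g$points[id, ], c(pre = 0.5, on = 0.5, post = 0))
  id2 <- nearest_grid_point(g, c(1, 0, 0))
  expect_equal(g$points[id2, ], c(pre = 1, on = 0, post = 0))
})
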