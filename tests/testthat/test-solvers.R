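test_that("single-trial terminal values and decision rules are exact", {
  sol <- single_default()
  b_pre <- sol$grid$points[, 1]
  # v_N = max(b(pre), 1 - b(pre)) and the attentional action at N is weak
  for (Y in 1:2)
    expect_equal(sol$values[10, , Y], pmax(b_pre, 1 - b_pre))
  expect_true(all(sol$policy[10, , ] == 1L))
  # report rule: no-signal exactly when b(pre) > 0.5
  expect_identical(sol$report_signal, !(b_pre > 0.5))
})

test_that("single-trial policy matches the regime structure at defaults", {
  sol <- single_default()
  # no belief state pays for strong at n = N0 = 3 when starting weak
  expect_equal(sum(sol$policy[3, , 1] == 2L), 0)
  # the strong region grows over the trial (weak attentional state)
  counts <- sapply(4:9, function(n) sum(sol$policy[n, , 1] == 2L))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[6], 0)
  # maintenance regions contain switch regions at every step
  for (n in 1:9) {
    sw <- sol$policy[n, , 1] == 2L
    expect_true(all(sol$policy[n, sw, 2] == 2L))
  }
})

test_that("penultimate-step policy matches a closed-form oracle", {
  # at n = N - 1 the continuation is analytic: P(correct report) given one
  # final observation, with pre and post both emitting mean 0
  sol <- single_default()
  g <- sol$grid
  p <- sol$params
  pc <- function(b, sig) stats::integrate(function(o)
    pmax(b[1] * stats::dnorm(o, 0, sig),
         b[2] * stats::dnorm(o, 1, sig) + b[3] * stats::dnorm(o, 0, sig)),
    -8, 9, rel.tol = 1e-10)$value
  set.seed(4)
  ids <- sample.int(nrow(g$points), 80)
  for (id in ids) {
    b <- g$points[id, ]
    margin <- (pc(b, p$sigma_s) + p$kappa) - pc(b, p$sigma_w)
    if (abs(margin) > 2e-3)   # skip knife-edge beliefs at grid resolution
      expect_equal(sol$policy[9, id, 1], if (margin > 0) 2L else 1L)
  }
})

test_that("average-reward solution maintains strong attention at the decision step", {
  avg <- avg_default()
  # from the strong state it is optimal to stay strong for every belief
  expect_true(all(avg$policy[10, , 2] == 2L))
  # from the weak state there is nothing to gain at the decision step
  expect_true(all(avg$policy[10, , 1] == 1L))
  expect_gt(avg$g_star, 0)
  expect_lt(avg$diagnostics$residual_span, 1e-9)
  # within-trial policy is essentially the episodic one
  single <- single_default()
  agree <- mean(avg$policy[1:9, , ] == single$policy[1:9, , ])
  expect_gt(agree, 0.9)
})

test_that("optimal average reward dominates both fixed policies", {
  avg <- avg_default()
  expect_gte(avg$g_star, fixed_default("always_weak")$g_star - 1e-12)
  expect_gte(avg$g_star, fixed_default("always_strong")$g_star - 1e-12)
})

test_that("with free strong attention the optimum equals always-strong", {
  p <- task_params(kappa = 0, epsilon = 0)
  g <- make_grid(0.05)
  q <- make_quadrature(p, 101)
  opt <- solve_average_reward(p, g, q)
  fs <- fixed_policy("always_strong", p, g, q)
  expect_equal(opt$g_star, fs$g_star, tolerance = 1e-8)
})

test_that("one-step signals are never worth engaging for at default costs", {
  p <- task_params(q = 1)
  sol <- solve_single_trial(p)
  st <- policy_stats(sol, start = "weak")
  expect_equal(st$strong_steps, 0)
  expect_equal(max(st$p_strong), 0)
})

test_that("fixed policies are constant with the shared report threshold", {
  fw <- fixed_default("always_weak")
  fs <- fixed_default("always_strong")
  expect_true(all(fw$policy == 1L))
  expect_true(all(fs$policy == 2L))
  expect_identical(fw$report_signal, fs$report_signal)
  expect_identical(fw$report_signal, !(fw$grid$points[, 1] > 0.5))
})

test_that("grid refinement changes single-trial values by less than 1e-2", {
  coarse <- single_default()
  p <- coarse$params
  fine <- solve_single_trial(p, make_grid(0.01), make_quadrature(p, 402))
  # coarse grid points are a subset of the fine lattice
  ids <- nearest_grid_point(fine$grid, coarse$grid$points)
  expect_equal(unname(fine$grid$points[ids, ]), unname(coarse$grid$points))
  for (Y in 1:2) {
    d <- abs(coarse$values[, , Y] - fine$values[, ids, Y])
    expect_lt(max(d), 1e-2)
  }
})

test_that("the average-reward solver reports non-convergence", {
  p <- task_params()
  g <- make_grid(0.25)
  expect_error(solve_average_reward(p, g, make_quadrature(p, 51), max_iter = 1),
               "did not converge")
})
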