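test_that("d-prime applies the standard quantile transform and rate correction", {
  expect_equal(dprime(0.4, 0.4, 100, 100), 0)
  expect_equal(dprime(0.84134, 0.15866, 1000, 1000), 2, tolerance = 1e-3)
  expect_equal(dprime(1, 0.1, 100, 200),
               stats::qnorm(0.995) - stats::qnorm(0.1))
  expect_equal(dprime(0.9, 0, 100, 200),
               stats::qnorm(0.9) - stats::qnorm(1 / 400))
  expect_error(dprime(0.5, 0.5, 0, 10), "positive")
})

test_that("episodic engagement follows the within-trial profile", {
  st <- policy_stats(single_default(), start = "weak")
  # certainty over the pre-signal steps leaves attention weak
  expect_equal(st$p_strong[1:5], rep(0, 5))
  # engagement rises mid-trial once evidence can favour a signal
  expect_true(all(st$p_strong[6:9] > 0))
  expect_true(all(diff(st$p_strong[6:9]) > 0))
  # nothing to gain at the decision step
  expect_equal(st$p_strong[10], 0)
})

test_that("exact forward statistics agree with Monte-Carlo simulation", {
  sol <- avg_default()
  st <- policy_stats(sol)
  run <- sim_default()
  s <- summarize_trials(run)
  # binomial 3 SE plus a small allowance for nearest-grid action lookup
  expect_lt(abs(st$H - s$H), 3 * s$se_H + 0.02)
  expect_lt(abs(st$F - s$F), 3 * s$se_F + 0.02)
  expect_lt(abs(st$strong_steps - s$strong_steps), 0.25)
  expect_lt(abs(st$reward_rate - s$reward_rate), 0.002)
})

test_that("simulated observations carry the believed evidence model", {
  # at the first step the belief is degenerate at pre and the action is the
  # policy's step-1 choice, so the log-evidence has a closed form
  run <- sim_default()
  a1 <- run$actions[, 1]
  for (ai in unique(a1)) {
    o1 <- run$obs[a1 == ai, 1]
    sd1 <- c(run$params$sigma_w, run$params$sigma_s)[ai]
    loglik <- stats::dnorm(o1, 0, sd1, log = TRUE)
    expected <- -0.5 * log(2 * pi * sd1^2) - 0.5
    expect_lt(abs(mean(loglik) - expected),
              3 * stats::sd(loglik) / sqrt(length(o1)))
  }
})

test_that("trial outcomes partition and rates match their definitions", {
  run <- sim_default()
  tr <- run$trials
  expect_true(all(tr$outcome %in% c("hit", "miss", "CR", "FA")))
  expect_identical(tr$outcome == "hit", tr$is_signal & tr$report == "signal")
  expect_identical(tr$outcome == "FA", !tr$is_signal & tr$report == "signal")
  s <- summarize_trials(run)
  expect_equal(s$H, sum(tr$outcome == "hit") / sum(tr$is_signal))
  expect_equal(s$F, sum(tr$outcome == "FA") / sum(!tr$is_signal))
  expect_equal(s$n_trials, nrow(tr))
})

test_that("detection improves with signal duration and later onset", {
  s <- summarize_trials(sim_default())
  hb <- s$hit_by_duration
  # hit rate non-decreasing in duration, 3 SE tolerance per adjacent pair
  for (k in seq_len(nrow(hb) - 1)) {
    se <- sqrt(hb$H[k] * (1 - hb$H[k]) / hb$n[k] +
               hb$H[k + 1] * (1 - hb$H[k + 1]) / hb$n[k + 1])
    expect_gt(hb$H[k + 1], hb$H[k] - 3 * se)
  }
  # conditional d' rises with duration overall
  expect_gt(hb$d_prime[nrow(hb)], hb$d_prime[1])
  # duration-3 signals are better detected with later onset
  ho <- s$hit_by_onset
  early <- ho$H[ho$L == 3 & ho$tau1 == 4]
  late <- ho$H[ho$L == 3 & ho$tau1 == 7]
  n3 <- sum(sim_default()$trials$L == 3 & sim_default()$trials$tau1 %in% c(4, 7),
            na.rm = TRUE)
  expect_gt(late, early - 3 * sqrt(0.5 * 0.5 / (n3 / 2)))
})

test_that("reward rate of the optimal policy dominates the fixed policies", {
  s <- summarize_trials(sim_default())
  for (kind in c("always_weak", "always_strong")) {
    base <- summarize_trials(run_trials(fixed_default(kind), 10000, seed = 42))
    se <- stats::sd(sim_default()$trials$reward) / sqrt(10000) / 10
    expect_gt(s$reward_rate, base$reward_rate - 3 * se)
  }
})

test_that("rare signals engage strong attention preferentially on signal trials", {
  p <- task_params(p1 = 0.15, epsilon = -0.005)
  sol <- cached("single_rare", solve_single_trial(p))
  run <- run_trials(sol, 10000, seed = 9)
  tr <- run$trials
  m1 <- mean(tr$strong_steps[tr$is_signal])
  m0 <- mean(tr$strong_steps[!tr$is_signal])
  se <- sqrt(stats::var(tr$strong_steps[tr$is_signal]) / sum(tr$is_signal) +
             stats::var(tr$strong_steps[!tr$is_signal]) / sum(!tr$is_signal))
  expect_gt(m1, m0 + 3 * se)
})

test_that("believing strong gives no advantage makes engagement worthless", {
  p <- task_params(sigma_s = 1)   # believed equal to sigma_w
  g <- make_grid(0.05)
  q <- make_quadrature(p, 101)
  sol <- solve_single_trial(p, g, q)
  expect_true(all(sol$policy == 1L))
  st <- policy_stats(sol, start = "weak")
  base <- policy_stats(fixed_policy("always_weak", p, g, q), start = "weak")
  expect_equal(st$H, base$H, tolerance = 1e-10)
  expect_equal(st$F, base$F, tolerance = 1e-10)
})

test_that("optogenetic manipulations reproduce the match/mismatch pattern", {
  ctrl <- opto_run("control")
  act <- opto_run("match_act")
  # matched activation: hits up (marginally), false alarms essentially flat
  se_h <- sqrt(ctrl$se_H^2 + act$se_H^2)
  expect_gt(act$H, ctrl$H - 3 * se_h)
  expect_lt(abs(act$F - ctrl$F), 0.05)
  expect_equal(act$strong_steps, 10)
  # matched suppression: hits down, false alarms up
  supp <- opto_run("match_supp")
  expect_lt(supp$H, ctrl$H - 3 * sqrt(ctrl$se_H^2 + supp$se_H^2))
  expect_gt(supp$F, ctrl$F + 3 * sqrt(ctrl$se_F^2 + supp$se_F^2))
  expect_equal(supp$strong_steps, 0)
  expect_error(run_optogenetic_condition("bogus", task_params()), "unknown")
})
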