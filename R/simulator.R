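# Draw one trial's latents using the current RNG stream.  Shared by
# sample_trials() and the simulator so that a given per-trial substream
# yields identical latents in both.
sample_one_trial <- function(params) {
  N <- params$N; N0 <- params$N0; N1 <- params$N1
  stages <- rep(1L, N - 1L)
  tau1 <- NA_integer_; len <- NA_integer_
  is_signal <- stats::runif(1) < params$p1
  if (is_signal) {
    tau1 <- N0 + sample.int(N1, 1L)
    len <- 1L
    while (tau1 + len - 1L < N - 1L && stats::runif(1) >= params$q)
      len <- len + 1L
    stages[tau1:(tau1 + len - 1L)] <- 2L
    if (tau1 + len - 1L < N - 1L) stages[(tau1 + len):(N - 1L)] <- 3L
  }
  list(stages = stages, is_signal = is_signal, tau1 = tau1, L = len)
}

outcome_label <- function(is_signal, report_signal) {
  ifelse(is_signal & report_signal, "hit",
    ifelse(is_signal & !report_signal, "miss",
      ifelse(!is_signal & !report_signal, "CR", "FA")))
}

#' Run simulated trials under a solved policy
#'
#' Trials are simulated in sequence: latent stages are drawn from the
#' generative parameters, the agent picks its attentional action from the
#' policy at the nearest grid belief, observations are drawn with the noise
#' of the actual attentional condition, beliefs are filtered with the
#' believed model, and the attentional state carries across trials with
#' spontaneous decay \code{delta} at each boundary.
#'
#' @param solution A \code{"sat_solution"} (drives actions and filtering).
#' @param n_trials Number of trials.
#' @param gen_params Generative parameters; defaults to the believed ones.
#' @param seed Root seed; trial \code{i} uses a deterministic substream.
#' @param start_Y Attentional state at the start of the first trial.
#' @param gen_sigma One of \code{"matched"} (observation noise follows the
#'   agent's actions), \code{"strong"} or \code{"weak"} (noise fixed
#'   regardless of the agent's actions, as under optogenetic clamping).
#' @param inference_sigma Optional \code{"strong"}/\code{"weak"}: a separate
#'   report is formed by filtering the same observations under the fixed
#'   believed noise (the mismatched-inference manipulation); the agent's
#'   actions still come from \code{solution}.
#' @return A \code{"sat_trials"} object: list with \code{trials} (data frame:
#'   is_signal, tau1, L, report, outcome, reward, strong_steps, Y1),
#'   \code{actions} (n x N, 1 = weak/2 = strong), \code{beliefs}
#'   (n x N x 3), \code{stages}, \code{obs}, and the parameter sets.
#' @export
run_trials <- function(solution, n_trials, gen_params = NULL, seed = 1L,
                       start_Y = c("weak", "strong"),
                       gen_sigma = c("matched", "strong", "weak"),
                       inference_sigma = NULL) {
  start_Y <- match.arg(start_Y)
  gen_sigma <- match.arg(gen_sigma)
  params <- solution$params
  if (is.null(gen_params)) gen_params <- params
  stopifnot(params$N == gen_params$N)
  grid <- solution$grid
  pol <- solution$policy
  costs <- cost_table(params)
  N <- params$N
  sig_gen <- c(gen_params$sigma_w, gen_params$sigma_s)
  infer_fixed <- !is.null(inference_sigma)
  if (infer_fixed) a_inf <- attn_index(inference_sigma)

  trials <- data.frame(is_signal = logical(n_trials), tau1 = NA_integer_,
                       L = NA_integer_, report = character(n_trials),
                       outcome = character(n_trials), reward = 0,
                       strong_steps = 0L, Y1 = character(n_trials))
  actions <- matrix(1L, n_trials, N)
  beliefs <- array(0, dim = c(n_trials, N, 3))
  stages <- matrix(1L, n_trials, N - 1L)
  obs <- matrix(NA_real_, n_trials, N - 1L)

  Y <- attn_index(start_Y)
  for (i in seq_len(n_trials)) {
    set.seed(trial_seed(seed, i))
    Y_start <- Y
    tr <- sample_one_trial(gen_params)
    b <- c(1, 0, 0)
    b_inf <- if (infer_fixed) c(1, 0, 0) else NULL
    rew <- 0
    for (n in seq_len(N - 1L)) {
      beliefs[i, n, ] <- b
      a <- pol[n, nearest_grid_point(grid, b), Y]
      actions[i, n] <- a
      rew <- rew + costs[Y, a]
      sd_n <- switch(gen_sigma, matched = sig_gen[a],
                     strong = sig_gen[2], weak = sig_gen[1])
      o <- stats::rnorm(1, mean = as.numeric(tr$stages[n] == 2L), sd = sd_n)
      obs[i, n] <- o
      b <- belief_update(b, ATTN[a], o, n, params)$belief
      if (infer_fixed)
        b_inf <- belief_update(b_inf, ATTN[a_inf], o, n, params)$belief
      Y <- a
    }
    beliefs[i, N, ] <- b
    aN <- pol[N, nearest_grid_point(grid, b), Y]
    actions[i, N] <- aN
    rew <- rew + costs[Y, aN]
    b_rep <- if (infer_fixed) b_inf else b
    report_signal <- !(b_rep[1] > 0.5)
    correct <- report_signal == tr$is_signal
    rew <- rew + as.numeric(correct)
    trials$is_signal[i] <- tr$is_signal
    trials$tau1[i] <- tr$tau1
    trials$L[i] <- tr$L
    trials$report[i] <- REPORTS[report_signal + 1L]
    trials$outcome[i] <- outcome_label(tr$is_signal, report_signal)
    trials$reward[i] <- rew
    trials$strong_steps[i] <- sum(actions[i, ] == 2L)
    trials$Y1[i] <- ATTN[Y_start]
    stages[i, ] <- tr$stages
    # attentional state entering the next trial, with boundary decay
    Y <- if (aN == 2L && stats::runif(1) >= params$delta) 2L else 1L
  }
  structure(list(trials = trials, actions = actions, beliefs = beliefs,
                 stages = stages, obs = obs, params = params,
                 gen_params = gen_params, gen_sigma = gen_sigma,
                 inference_sigma = inference_sigma),
            class = "sat_trials")
}

#' @export
print.sat_trials <- function(x, ...) {
  cat(sprintf("%d simulated SAT trials (%s observation noise)\n",
              nrow(x$trials), x$gen_sigma))
  print(table(x$trials$outcome))
  invisible(x)
}

#' Sensitivity index d'
#'
#' \code{d' = z(H) - z(F)} with the standard correction replacing rates of 0
#' and 1 by \code{1/(2m)} and \code{1 - 1/(2m)}, where m is the relevant
#' trial count.
#'
#' @param H Hit rate.
#' @param F False-alarm rate.
#' @param n_signal Number of signal trials behind \code{H}.
#' @param n_nonsignal Number of non-signal trials behind \code{F}.
#' @return The sensitivity d'.
#' @export
dprime <- function(H, F, n_signal, n_nonsignal) {
  if (n_signal <= 0 || n_nonsignal <= 0) stop("trial counts must be positive")
  fix <- function(r, m) min(max(r, 1 / (2 * m)), 1 - 1 / (2 * m))
  stats::qnorm(fix(H, n_signal)) - stats::qnorm(fix(F, n_nonsignal))
}

#' Summarize simulated trials
#'
#' Hit/false-alarm rates and d', per-step probability of the strong action,
#' expected strong steps per trial, reward rate per step, and hit rates and
#' d' conditional on signal duration and onset (conditional d' combines the
#' duration-specific hit rate with the common false-alarm rate).
#'
#' @param x A \code{"sat_trials"} object.
#' @return A \code{"sat_summary"} list.
#' @export
summarize_trials <- function(x) {
  tr <- x$trials
  if (!nrow(tr)) stop("no trials to summarize")
  n_sig <- sum(tr$is_signal); n_non <- sum(!tr$is_signal)
  H <- if (n_sig) mean(tr$outcome[tr$is_signal] == "hit") else NA_real_
  F <- if (n_non) mean(tr$outcome[!tr$is_signal] == "FA") else NA_real_
  dp <- if (n_sig && n_non) dprime(H, F, n_sig, n_non) else NA_real_
  sig <- tr[tr$is_signal, ]
  by_dur <- if (nrow(sig)) {
    durs <- sort(unique(sig$L))
    data.frame(L = durs,
               H = vapply(durs, function(d) mean(sig$outcome[sig$L == d] == "hit"),
                          numeric(1)),
               n = vapply(durs, function(d) sum(sig$L == d), numeric(1)))
  } else NULL
  if (!is.null(by_dur) && n_non)
    by_dur$d_prime <- vapply(seq_len(nrow(by_dur)), function(k)
      dprime(by_dur$H[k], F, by_dur$n[k], n_non), numeric(1))
  by_onset <- if (nrow(sig)) stats::aggregate(
    list(H = sig$outcome == "hit"), by = list(tau1 = sig$tau1, L = sig$L),
    FUN = mean) else NULL
  out <- list(n_trials = nrow(tr), n_signal = n_sig, n_nonsignal = n_non,
              H = H, F = F, d_prime = dp,
              se_H = if (n_sig) sqrt(H * (1 - H) / n_sig) else NA_real_,
              se_F = if (n_non) sqrt(F * (1 - F) / n_non) else NA_real_,
              p_strong = colMeans(x$actions == 2L),
              strong_steps = mean(tr$strong_steps),
              reward_rate = mean(tr$reward) / x$params$N,
              hit_by_duration = by_dur, hit_by_onset = by_onset)
  class(out) <- "sat_summary"
  out
}

#' @export
print.sat_summary <- function(x, ...) {
  cat(sprintf("SAT performance over %d trials (%d signal, %d non-signal)\n",
              x$n_trials, x$n_signal, x$n_nonsignal))
  cat(sprintf("  H = %.3f (SE %.3f), F = %.3f (SE %.3f), d' = %.3f\n",
              x$H, x$se_H, x$F, x$se_F, x$d_prime))
  cat(sprintf("  strong steps per trial = %.3f; reward rate per step = %.4f\n",
              x$strong_steps, x$reward_rate))
  cat("  P(a = strong) by step:", paste(sprintf("%.2f", x$p_strong),
                                        collapse = " "), "\n")
  invisible(x)
}

.opto_conditions <- c("control", "match_act", "match_supp",
                      "mismatch_obs_act", "mismatch_obs_supp",
                      "mismatch_inf_act", "mismatch_inf_supp")

#' Optogenetic-style match/mismatch manipulations
#'
#' Simulates one condition of the manipulation experiment in which the actual
#' and believed quality of observations may be decoupled:
#' \describe{
#'   \item{control}{observations generated under the optimal policy and
#'     believed to be.}
#'   \item{match_act / match_supp}{always-strong / always-weak generation
#'     with matched inference (the agent runs that fixed policy).}
#'   \item{mismatch_obs_act / mismatch_obs_supp}{the agent runs (and believes)
#'     the optimal policy, but observation noise is clamped to the strong /
#'     weak level.}
#'   \item{mismatch_inf_act / mismatch_inf_supp}{observations are generated
#'     under the optimal policy's actions, but the report is formed by
#'     filtering with an assumed always-strong / always-weak noise model.}
#' }
#'
#' @param condition One of the seven condition names above.
#' @param params A \code{\link{task_params}} object.
#' @param n_trials Trials per condition (default 10000).
#' @param seed Root seed.
#' @param solutions Optional pre-solved list with elements \code{optimal},
#'   \code{always_strong}, \code{always_weak} (average-reward solutions) to
#'   avoid re-solving.
#' @param grid,quad Discretization used if solutions must be solved here.
#' @return A \code{"sat_summary"} with the condition name attached.
#' @export
run_optogenetic_condition <- function(condition, params, n_trials = 10000,
                                      seed = 1L, solutions = NULL,
                                      grid = make_grid(),
                                      quad = make_quadrature(params)) {
  if (!condition %in% .opto_conditions)
    stop("unknown condition: ", condition)
  if (is.null(solutions))
    solutions <- list(optimal = solve_average_reward(params, grid, quad),
                      always_strong = fixed_policy("always_strong", params, grid, quad),
                      always_weak = fixed_policy("always_weak", params, grid, quad))
  run <- switch(condition,
    control = run_trials(solutions$optimal, n_trials, seed = seed),
    match_act = run_trials(solutions$always_strong, n_trials, seed = seed),
    match_supp = run_trials(solutions$always_weak, n_trials, seed = seed),
    mismatch_obs_act = run_trials(solutions$optimal, n_trials, seed = seed,
                                  gen_sigma = "strong"),
    mismatch_obs_supp = run_trials(solutions$optimal, n_trials, seed = seed,
                                   gen_sigma = "weak"),
    mismatch_inf_act = run_trials(solutions$optimal, n_trials, seed = seed,
                                  inference_sigma = "strong"),
    mismatch_inf_supp = run_trials(solutions$optimal, n_trials, seed = seed,
                                   inference_sigma = "weak"))
  out <- summarize_trials(run)
  out$condition <- condition
  out
}

#' Run all optogenetic-style conditions
#'
#' @inheritParams run_optogenetic_condition
#' @param conditions Conditions to run (default all seven).
#' @return Data frame with one row per condition: H, F and their binomial
#'   standard errors, d', and strong steps per trial.
#' @export
run_optogenetics <- function(params, n_trials = 10000, seed = 1L,
                             conditions = .opto_conditions,
                             grid = make_grid(),
                             quad = make_quadrature(params)) {
  solutions <- list(optimal = solve_average_reward(params, grid, quad),
                    always_strong = fixed_policy("always_strong", params, grid, quad),
                    always_weak = fixed_policy("always_weak", params, grid, quad))
  rows <- lapply(conditions, function(cond) {
    s <- run_optogenetic_condition(cond, params, n_trials, seed, solutions)
    data.frame(condition = cond, H = s$H, se_H = s$se_H, F = s$F,
               se_F = s$se_F, d_prime = s$d_prime,
               strong_steps = s$strong_steps)
  })
  do.call(rbind, rows)
}
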