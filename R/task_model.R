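#' Signal onset distribution
#'
#' A signal, if one occurs, arrives uniformly at one of the \code{N1} steps
#' \code{N0 < n < N}.
#'
#' @param params A \code{\link{task_params}} object.
#' @return Numeric vector of length \code{N}: \code{P(onset = n | signal)}.
#' @export
signal_onset_pmf <- function(params) {
  pmf <- numeric(params$N)
  pmf[(params$N0 + 1):(params$N - 1)] <- 1 / params$N1
  pmf
}

#' Signal arrival hazard
#'
#' Conditional probability that the signal arrives at step \code{n} given it
#' has not arrived earlier, taking the signal probability \code{p1} into
#' account:
#' \deqn{\lambda_n = \frac{p_1/N_1}{1 - p_1 (n - N_0 - 1)/N_1}}
#' for \code{N0 < n < N} and 0 otherwise.  The hazard is non-decreasing over
#' the arrival window.
#'
#' @param n Step index (vectorized), in \code{1..N}.
#' @param params A \code{\link{task_params}} object.
#' @return Hazard value(s) in [0, 1].
#' @export
hazard <- function(n, params) {
  if (any(n < 1L | n > params$N)) stop("step index out of range 1..N")
  lam <- numeric(length(n))
  inside <- n > params$N0 & n < params$N
  ni <- n[inside]
  lam[inside] <- (params$p1 / params$N1) /
    (1 - params$p1 * (ni - params$N0 - 1) / params$N1)
  lam
}

#' Marginal probability that the signal is on at step n
#'
#' \deqn{P(X_n = on) = \frac{p_1}{N_1} \sum_{N_0 < s \le n} (1-q)^{n-s}}
#' With \code{q = 0} this rises to \code{p1} just before the decision step;
#' with \code{q = 1} it is flat at \code{p1/N1} over the arrival window.
#'
#' @inheritParams hazard
#' @return Probability value(s).
#' @export
prob_on <- function(n, params) {
  if (any(n < 1L | n > params$N)) stop("step index out of range 1..N")
  vapply(n, function(nn) {
    if (nn <= params$N0 || nn >= params$N) return(0)
    s <- (params$N0 + 1):nn
    (params$p1 / params$N1) * sum((1 - params$q)^(nn - s))
  }, numeric(1))
}

#' Signal duration distribution
#'
#' Probability that a signal lasts \code{l} steps, conditioned on a signal
#' occurring.  Truncation by the fixed trial length makes this deviate from
#' the geometric distribution with parameter \code{q}:
#' \deqn{P(L = l | signal) = \frac{(1-q)^{l-1}}{N_1}\,(1 + (N_1 - l) q)}
#' for \code{l} in \code{1..N1}, zero otherwise.
#'
#' @param l Duration in steps (vectorized).
#' @param params A \code{\link{task_params}} object.
#' @return Probability value(s).
#' @export
duration_pmf <- function(l, params) {
  out <- numeric(length(l))
  ok <- l >= 1 & l <= params$N1
  lo <- l[ok]
  out[ok] <- (1 - params$q)^(lo - 1) / params$N1 * (1 + (params$N1 - lo) * params$q)
  out
}

#' All trial-level distributions of a configuration
#'
#' @param params A \code{\link{task_params}} object.
#' @return List with \code{onset_pmf} (length \code{N}), \code{hazard}
#'   (length \code{N}), \code{p_on} (length \code{N}) and \code{duration_pmf}
#'   (length \code{N1}).
#' @export
trial_distributions <- function(params) {
  n <- seq_len(params$N)
  list(onset_pmf = signal_onset_pmf(params),
       hazard = hazard(n, params),
       p_on = prob_on(n, params),
       duration_pmf = duration_pmf(seq_len(params$N1), params))
}

# Deterministic per-trial substream: trial i is reproducible regardless of
# how many trials are drawn around it.
trial_seed <- function(root_seed, i) {
  as.integer((as.double(root_seed) * 1000003 + i * 7919) %% 2147483629)
}

#' Sample latent stage sequences for SAT trials
#'
#' Draws the experimenter-side latents of \code{n_trials} trials: whether a
#' signal occurs (probability \code{p1}), its onset (uniform over the arrival
#' window) and its duration (per-step offset probability \code{q}, forced off
#' before the decision step).  Stages are recorded for steps
#' \code{1..N-1}; the decision step carries no stage draw.
#'
#' @param params A \code{\link{task_params}} object.
#' @param n_trials Number of trials.
#' @param seed Root seed; each trial uses a deterministic substream.
#' @return List with \code{stages} (\code{n_trials x (N-1)} integer matrix,
#'   1 = pre, 2 = on, 3 = post) and a data frame \code{meta} with columns
#'   \code{is_signal, tau1, tau2, L} (\code{tau2} is the offset step, i.e.
#'   the first step at which the signal is off again; NA on non-signal
#'   trials).
#' @export
sample_trials <- function(params, n_trials, seed = 1L) {
  N <- params$N; N0 <- params$N0; N1 <- params$N1
  stages <- matrix(1L, n_trials, N - 1L)
  is_signal <- logical(n_trials)
  tau1 <- rep(NA_integer_, n_trials)
  L <- rep(NA_integer_, n_trials)
  for (i in seq_len(n_trials)) {
    set.seed(trial_seed(seed, i))
    if (stats::runif(1) < params$p1) {
      is_signal[i] <- TRUE
      t1 <- N0 + sample.int(N1, 1L)
      len <- 1L
      # per on-step offset with probability q; forced off entering step N
      while (t1 + len - 1L < N - 1L && stats::runif(1) >= params$q)
        len <- len + 1L
      stages[i, t1:(t1 + len - 1L)] <- 2L
      if (t1 + len - 1L < N - 1L) stages[i, (t1 + len):(N - 1L)] <- 3L
      tau1[i] <- t1; L[i] <- len
    }
  }
  list(stages = stages,
       meta = data.frame(is_signal = is_signal, tau1 = tau1,
                         tau2 = tau1 + L, L = L))
}
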