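#' Configuration of a session with nonstationary estimated signal probability
#'
#' In the sequential regime the agent's estimate of the per-trial signal
#' probability switches between two low values while the true generative
#' probability stays fixed (and typically much higher).  Separate
#' average-reward policies are solved for the two estimate levels on a shared
#' grid.
#'
#' @param p1_low,p1_high The two estimate levels (defaults 0.1 and 0.15).
#' @param gen_p1 True generative signal probability (default 0.5).
#' @param params Shared task parameters (q, sigmas, costs, delta); the
#'   defaults here are the sequential-regime values with maintenance cost
#'   \code{epsilon = -0.005}.
#' @param grid,quad Discretization shared by both policies.
#' @param solutions Optional pre-solved list with elements \code{low} and
#'   \code{high}; solved here if missing.
#' @return An object of class \code{"sat_session_config"}.
#' @export
session_config <- function(p1_low = 0.1, p1_high = 0.15, gen_p1 = 0.5,
                           params = task_params(epsilon = -0.005),
                           grid = make_grid(),
                           quad = make_quadrature(params),
                           solutions = NULL) {
  if (p1_low > p1_high) stop("p1_low must be <= p1_high")
  params_low <- do.call(task_params, utils::modifyList(
    params[.config_keys], list(p1 = p1_low)))
  params_high <- do.call(task_params, utils::modifyList(
    params[.config_keys], list(p1 = p1_high)))
  gen_params <- do.call(task_params, utils::modifyList(
    params[.config_keys], list(p1 = gen_p1)))
  if (is.null(solutions))
    solutions <- list(low = solve_average_reward(params_low, grid, quad),
                      high = solve_average_reward(params_high, grid, quad))
  structure(list(p1_low = p1_low, p1_high = p1_high, gen_p1 = gen_p1,
                 params_low = params_low, params_high = params_high,
                 gen_params = gen_params, grid = grid, quad = quad,
                 solutions = solutions),
            class = "sat_session_config")
}

#' @export
print.sat_session_config <- function(x, ...) {
  cat(sprintf("sequential session: p1-hat in {%g, %g}, generative p1 = %g\n",
              x$p1_low, x$p1_high, x$gen_p1))
  cat(sprintf("  shared params: q = %g, sigma_s = %g, kappa = %g, epsilon = %g, delta = %g\n",
              x$gen_params$q, x$gen_params$sigma_s, x$gen_params$kappa,
              x$gen_params$epsilon, x$gen_params$delta))
  invisible(x)
}

#' Run a session with trial-to-trial switching of the estimated signal rate
#'
#' Trials are generated with the true \code{gen_p1}; within each trial the
#' agent filters and acts under the hazard and policy of its current
#' estimate.  Two rules move the estimate: (1) if the estimate is low and a
#' weak-to-strong attentional shift occurs mid-trial, the estimate jumps to
#' the high level immediately for the rest of the trial; (2) end-of-trial
#' feedback sets the estimate to the high level after a signal trial and the
#' low level after a non-signal trial.  The attentional state carries across
#' trials with boundary decay \code{delta}.
#'
#' @param config A \code{\link{session_config}}.
#' @param n_trials Number of trials.
#' @param seed Root seed.
#' @return A \code{"sat_session"}: list with \code{trials} (data frame with
#'   is_signal, tau1, L, report, outcome, Y1, shift — whether a weak-to-strong
#'   shift occurred — p1_init, the estimate in force at trial start, and
#'   \code{class}, the trial-history label),
#'   \code{actions} (n x N), \code{p1_hat} (n x N, estimate in force at each
#'   step), and the config.
#' @export
run_session <- function(config, n_trials = 10000, seed = 1L) {
  stopifnot(inherits(config, "sat_session_config"))
  grid <- config$grid
  pols <- list(config$solutions$low, config$solutions$high)
  pars <- list(config$params_low, config$params_high)
  gen <- config$gen_params
  N <- gen$N
  sig <- c(gen$sigma_w, gen$sigma_s)

  trials <- data.frame(is_signal = logical(n_trials), tau1 = NA_integer_,
                       L = NA_integer_, report = character(n_trials),
                       outcome = character(n_trials), Y1 = character(n_trials),
                       shift = logical(n_trials), p1_init = 0)
  actions <- matrix(1L, n_trials, N)
  p1_path <- matrix(0, n_trials, N)

  Y <- 1L
  level <- 1L  # start at the low estimate
  for (i in seq_len(n_trials)) {
    set.seed(trial_seed(seed, i))
    tr <- sample_one_trial(gen)
    b <- c(1, 0, 0)
    Y_start <- Y
    shift <- FALSE
    trials$p1_init[i] <- c(config$p1_low, config$p1_high)[level]
    for (n in seq_len(N - 1L)) {
      a <- pols[[level]]$policy[n, nearest_grid_point(grid, b), Y]
      if (a == 2L && Y == 1L && level == 1L) {
        level <- 2L  # rule 1: mid-trial jump of the estimate
        shift <- TRUE
      }
      p1_path[i, n] <- c(config$p1_low, config$p1_high)[level]
      actions[i, n] <- a
      o <- stats::rnorm(1, mean = as.numeric(tr$stages[n] == 2L), sd = sig[a])
      b <- belief_update(b, ATTN[a], o, n, pars[[level]])$belief
      if (a == 2L && Y == 1L && !shift) shift <- TRUE
      Y <- a
    }
    aN <- pols[[level]]$policy[N, nearest_grid_point(grid, b), Y]
    actions[i, N] <- aN
    p1_path[i, N] <- c(config$p1_low, config$p1_high)[level]
    report_signal <- !(b[1] > 0.5)
    trials$is_signal[i] <- tr$is_signal
    trials$tau1[i] <- tr$tau1
    trials$L[i] <- tr$L
    trials$report[i] <- REPORTS[report_signal + 1L]
    trials$outcome[i] <- outcome_label(tr$is_signal, report_signal)
    trials$Y1[i] <- ATTN[Y_start]
    trials$shift[i] <- shift
    # rule 2: feedback resets the estimate for the next trial
    level <- if (tr$is_signal) 2L else 1L
    Y <- if (aN == 2L && stats::runif(1) >= gen$delta) 2L else 1L
  }
  trials$class <- classify_outcomes(trials$outcome, trials$report)
  structure(list(trials = trials, actions = actions, p1_hat = p1_path,
                 config = config),
            class = "sat_session")
}

#' @export
print.sat_session <- function(x, ...) {
  cat(sprintf("sequential SAT session: %d trials\n", nrow(x$trials)))
  print(table(x$trials$class, useNA = "ifany"))
  invisible(x)
}

# Core classification given outcome and report vectors; first trial unlabeled.
classify_outcomes <- function(outcome, report) {
  n <- length(outcome)
  cls <- rep(NA_character_, n)
  if (n < 2L) return(cls)
  prev_out <- outcome[-n]
  prev_rep <- report[-n]
  cur <- outcome[-1L]
  lab <- rep(NA_character_, n - 1L)
  lab[cur == "hit" & prev_rep == "no_signal"] <- "incongruent_hit"
  lab[cur == "hit" & prev_out == "hit"] <- "consecutive_hit"
  lab[cur == "CR" & prev_out == "hit"] <- "incongruent_CR"
  lab[cur == "CR" & prev_rep == "no_signal"] <- "congruent_CR"
  cls[-1L] <- lab
  cls
}

#' Classify trials by their immediate history
#'
#' A hit preceded by a reported non-signal is an incongruent hit; a hit
#' preceded by a hit is a consecutive hit; a correct rejection preceded by a
#' hit is an incongruent correct rejection; a correct rejection preceded by a
#' reported non-signal is a congruent correct rejection.  The first trial is
#' unlabeled, as are trials outside these four classes.
#'
#' @param x A \code{"sat_session"} or \code{"sat_trials"} object.
#' @return Character vector of class labels (NA where unlabeled).
#' @export
classify_trials <- function(x) {
  tr <- x$trials
  classify_outcomes(tr$outcome, tr$report)
}

#' Baseline-corrected phasic acetylcholine proxy
#'
#' Treating the strong attentional action as the ACh report, computes the
#' class-averaged per-step indicator of choosing strong, aligned at the
#' signal onset (signal trials) or the average onset time (non-signal
#' trials), baseline-corrected by the mean over the 3 steps preceding the
#' alignment point.  The trace extends a few steps into the following trial
#' so that attentional shifts triggered by end-of-trial feedback are visible.
#'
#' @param session A \code{"sat_session"} (or any object with \code{trials}
#'   and \code{actions} of the same layout).
#' @param class_label One of the \code{\link{classify_trials}} labels.
#' @param extend Steps of the following trial appended to each trace
#'   (default 3).
#' @return A \code{"sat_ach_trace"} data frame with columns \code{offset}
#'   (step minus alignment point), \code{mean}, \code{se} and \code{n}.
#' @export
ach_trace <- function(session, class_label, extend = 3L) {
  tr <- session$trials
  acts <- session$actions
  N <- ncol(acts)
  idx <- which(!is.na(tr$class) & tr$class == class_label)
  if (extend > 0L) idx <- idx[idx < nrow(tr)]
  if (!length(idx)) stop("no trials of class ", class_label)
  gen <- session$config$gen_params
  # average onset time, rounded half-up, for aligning non-signal trials
  avg_onset <- floor(gen$N0 + (gen$N1 + 1) / 2 + 0.5)
  offs <- list(); vals <- list()
  for (j in seq_along(idx)) {
    i <- idx[j]
    ind <- c(acts[i, ] == 2L,
             if (extend > 0L) acts[i + 1L, seq_len(extend)] == 2L)
    align <- if (tr$is_signal[i]) tr$tau1[i] else avg_onset
    base <- mean(ind[max(1L, align - 3L):(align - 1L)])
    offs[[j]] <- seq_along(ind) - align
    vals[[j]] <- as.numeric(ind) - base
  }
  off <- unlist(offs); val <- unlist(vals)
  agg_mean <- tapply(val, off, mean)
  agg_n <- tapply(val, off, length)
  agg_sd <- tapply(val, off, stats::sd)
  out <- data.frame(offset = as.integer(names(agg_mean)),
                    mean = as.numeric(agg_mean),
                    se = as.numeric(agg_sd) / sqrt(as.numeric(agg_n)),
                    n = as.numeric(agg_n))
  out <- out[order(out$offset), ]
  rownames(out) <- NULL
  attr(out, "class_label") <- class_label
  attr(out, "n_trials") <- length(idx)
  class(out) <- c("sat_ach_trace", "data.frame")
  out
}

#' @export
plot.sat_ach_trace <- function(x, ...) {
  graphics::plot(x$offset, x$mean, type = "b", pch = 16,
                 xlab = "step relative to (average) signal onset",
                 ylab = "ACh proxy (baseline-corrected P(a = strong))",
                 main = attr(x, "class_label"), ...)
  graphics::arrows(x$offset, x$mean - x$se, x$offset, x$mean + x$se,
                   angle = 90, code = 3, length = 0.02, col = "grey50")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
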