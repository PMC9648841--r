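# Tie tolerance for action selection: when the two action values are equal
# within this, the cost-free weak action is chosen.
.tie_tol <- 1e-12

grid_origin_id <- function(grid) grid$lookup[grid$M + 1L, 1L]

# One backward-induction pass through a trial.
#
# h: continuation values (v at the start of the next trial) for next-trial
#    attentional state (weak, strong); only used when continuing = TRUE.
# policy: NULL for a greedy pass, or an N x P x 2 integer array (1 = weak,
#    2 = strong) for policy evaluation.
# Returns values, policy, the report rule, and v at (n = 1, b = (1,0,0), Y).
backward_pass <- function(params, grid, Phi, h = c(0, 0),
                          continuing = FALSE, policy = NULL) {
  N <- params$N
  P <- nrow(grid$points)
  b_pre <- grid$points[, 1]
  costs <- cost_table(params)
  v <- array(0, dim = c(N, P, 2))
  pol <- if (is.null(policy)) array(1L, dim = c(N, P, 2)) else policy
  report_signal <- !(b_pre > 0.5)
  rep_val <- pmax(b_pre, 1 - b_pre)

  # decision step: report value plus the attentional action's cost and
  # (multi-trial case) its cross-trial continuation
  cont <- if (continuing) c(h[1], (1 - params$delta) * h[2] + params$delta * h[1])
          else c(0, 0)
  for (Y in 1:2) {
    q1 <- costs[Y, 1] + cont[1]
    q2 <- costs[Y, 2] + cont[2]
    if (is.null(policy)) pol[N, , Y] <- if (q2 > q1 + .tie_tol) 2L else 1L
    qa <- ifelse(pol[N, , Y] == 2L, q2, q1)
    v[N, , Y] <- rep_val + qa
  }

  for (n in (N - 1L):1L) {
    # expected continuation under each action (successor Y equals the action),
    # shared across the current Y since the cost enters additively
    base1 <- as.numeric(Phi[[n]][[1]] %*% v[n + 1L, , 1])
    base2 <- as.numeric(Phi[[n]][[2]] %*% v[n + 1L, , 2])
    for (Y in 1:2) {
      q1 <- costs[Y, 1] + base1
      q2 <- costs[Y, 2] + base2
      if (is.null(policy))
        pol[n, , Y] <- ifelse(q2 > q1 + .tie_tol, 2L, 1L)
      v[n, , Y] <- ifelse(pol[n, , Y] == 2L, q2, q1)
    }
  }
  id0 <- grid_origin_id(grid)
  list(values = v, policy = pol, report_signal = report_signal,
       v1 = c(v[1L, id0, 1], v[1L, id0, 2]))
}

new_solution <- function(params, grid, quad, mode, kind, pass, g_star = NULL,
                         h = NULL, diagnostics = list()) {
  structure(list(params = params, grid = grid, quad = quad, mode = mode,
                 kind = kind, values = pass$values, policy = pass$policy,
                 report_signal = pass$report_signal, g_star = g_star, h = h,
                 diagnostics = diagnostics),
            class = "sat_solution")
}

#' Solve a single trial by backward induction
#'
#' Finite-horizon optimal policy for one isolated trial.  At the decision
#' step the attentional action is always weak (it has no informational or
#' future value) and the report is "no signal" exactly when the belief in the
#' pre-signal stage exceeds 0.5, so the terminal value is
#' \code{max(b(pre), 1 - b(pre))}.  Earlier steps maximize attentional cost
#' plus expected continuation over the discretized belief transition.
#'
#' @param params A \code{\link{task_params}} object.
#' @param grid A \code{\link{make_grid}} object (default spacing 0.02).
#' @param quad A \code{\link{make_quadrature}} spec (default 201 nodes).
#' @return A \code{"sat_solution"} object with the value table
#'   (\code{values[n, grid id, Y]}), the policy (1 = weak, 2 = strong), and
#'   the report rule.
#' @export
solve_single_trial <- function(params, grid = make_grid(),
                               quad = make_quadrature(params)) {
  Phi <- transition_operators(grid, params, quad)
  pass <- backward_pass(params, grid, Phi, continuing = FALSE)
  new_solution(params, grid, quad, mode = "single", kind = "optimal", pass)
}

# Affine policy evaluation of a full-trial policy: the map from next-trial
# start values h to current start values v1 is affine, v1 = r + A h, where
# A[Y, Y'] is the probability the next trial starts in Y'.  Three passes
# identify r and the columns of A.
evaluate_trial_policy <- function(params, grid, Phi, policy) {
  p0 <- backward_pass(params, grid, Phi, h = c(0, 0), continuing = TRUE,
                      policy = policy)$v1
  pw <- backward_pass(params, grid, Phi, h = c(1, 0), continuing = TRUE,
                      policy = policy)$v1
  ps <- backward_pass(params, grid, Phi, h = c(0, 1), continuing = TRUE,
                      policy = policy)$v1
  list(r = p0, A = cbind(pw - p0, ps - p0))
}

# Gain and bias of the embedded two-state (start-of-trial Y) chain under a
# fixed trial policy, normalizing the bias of the weak start state to 0.
gain_bias <- function(r, A, N) {
  denom <- 1 - A[2, 2] + A[1, 2]
  if (abs(denom) < 1e-14)
    stop("cross-trial chain is not unichain; is delta = 0 with an absorbing strong state?")
  hs <- (r[2] - r[1]) / denom
  g_trial <- r[1] + A[1, 2] * hs
  list(h = c(0, hs), g_trial = g_trial, g_star = g_trial / N)
}

#' Solve the continuing, average-reward problem
#'
#' Optimal policy maximizing long-run reward per step over continuing trials.
#' Beliefs reset to certainty in the pre-signal stage at each trial start, so
#' the only state carried across trials is the attentional state (with
#' spontaneous strong-to-weak decay \code{delta} at the boundary).  The
#' solver alternates greedy backward induction through the trial with exact
#' policy evaluation on the embedded two-state cross-trial chain, and
#' terminates when the policy is stable and the bias has converged.
#'
#' @inheritParams solve_single_trial
#' @param tol Convergence tolerance on the differential value of the strong
#'   start state.
#' @param max_iter Maximum policy-iteration sweeps.
#' @return A \code{"sat_solution"} with \code{g_star} (average reward per
#'   step), differential values, policy, and diagnostics (iteration count and
#'   Bellman residual span over the start states).
#' @export
solve_average_reward <- function(params, grid = make_grid(),
                                 quad = make_quadrature(params),
                                 tol = 1e-9, max_iter = 200) {
  Phi <- transition_operators(grid, params, quad)
  h <- c(0, 0)
  pol_prev <- NULL
  gb <- NULL
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    greedy <- backward_pass(params, grid, Phi, h = h, continuing = TRUE)
    ev <- evaluate_trial_policy(params, grid, Phi, greedy$policy)
    gb <- gain_bias(ev$r, ev$A, params$N)
    stable <- !is.null(pol_prev) && identical(greedy$policy, pol_prev) &&
      abs(gb$h[2] - h[2]) < tol * max(1, abs(gb$h[2]))
    h <- gb$h
    pol_prev <- greedy$policy
    if (stable) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("average-reward solver did not converge in %d sweeps (last bias %.6g)",
                 max_iter, h[2]))
  final <- backward_pass(params, grid, Phi, h = h, continuing = TRUE)
  resid <- final$v1 - h - gb$g_trial
  new_solution(params, grid, quad, mode = "average", kind = "optimal", final,
               g_star = gb$g_star, h = h,
               diagnostics = list(iterations = iter,
                                  residual_span = diff(range(resid))))
}

#' Fixed reference policies
#'
#' The always-weak and always-strong policies used as comparators in the
#' parameter sweeps: a constant attentional action everywhere, with the usual
#' Bayes-optimal 0.5 report threshold applied to beliefs filtered under the
#' corresponding observation noise.  The policy is evaluated (not optimized)
#' in the continuing, average-reward sense so that \code{g_star} is
#' comparable to the optimal solution's.
#'
#' @param kind \code{"always_weak"} or \code{"always_strong"}.
#' @inheritParams solve_single_trial
#' @return A \code{"sat_solution"} with the forced policy and its average
#'   reward rate.
#' @export
fixed_policy <- function(kind = c("always_weak", "always_strong"), params,
                         grid = make_grid(), quad = make_quadrature(params)) {
  kind <- match.arg(kind)
  Phi <- transition_operators(grid, params, quad)
  a <- if (kind == "always_strong") 2L else 1L
  P <- nrow(grid$points)
  policy <- array(a, dim = c(params$N, P, 2))
  ev <- evaluate_trial_policy(params, grid, Phi, policy)
  gb <- gain_bias(ev$r, ev$A, params$N)
  pass <- backward_pass(params, grid, Phi, h = gb$h, continuing = TRUE,
                        policy = policy)
  new_solution(params, grid, quad, mode = "average", kind = kind, pass,
               g_star = gb$g_star, h = gb$h,
               diagnostics = list(iterations = 1L, residual_span = 0))
}

#' @export
print.sat_solution <- function(x, ...) {
  cat(sprintf("SAT belief-MDP solution (%s, %s policy)\n", x$mode, x$kind))
  cat(sprintf("  grid: delta_b = %g (%d points); quadrature: %d nodes\n",
              x$grid$delta_b, nrow(x$grid$points), length(x$quad$nodes)))
  if (!is.null(x$g_star))
    cat(sprintf("  average reward per step g* = %.6f\n", x$g_star))
  if (length(x$diagnostics))
    cat(sprintf("  solver: %d sweep(s), residual span %.3g\n",
                x$diagnostics$iterations, x$diagnostics$residual_span))
  invisible(x)
}

#' @export
summary.sat_solution <- function(object, ...) {
  N <- object$params$N
  frac <- sapply(seq_len(N), function(n)
    c(weak = mean(object$policy[n, , 1] == 2L),
      strong = mean(object$policy[n, , 2] == 2L)))
  out <- list(solution = object, strong_fraction = t(frac))
  class(out) <- "summary.sat_solution"
  out
}

#' @export
print.summary.sat_solution <- function(x, ...) {
  print(x$solution)
  cat("  fraction of grid beliefs where strong is chosen, by step and current Y:\n")
  tab <- round(x$strong_fraction, 3)
  rownames(tab) <- paste0("n=", seq_len(nrow(tab)))
  print(tab)
  invisible(x)
}

#' Plot the optimal policy over the belief simplex
#'
#' Scatter of the grid beliefs in 2-D simplex coordinates at one time step,
#' darker where strong attention is chosen, one panel per current attentional
#' state.
#'
#' @param x A \code{"sat_solution"}.
#' @param n Step to display (default the penultimate step).
#' @param ... Passed to \code{plot}.
#' @export
plot.sat_solution <- function(x, n = x$params$N - 1L, ...) {
  pts <- x$grid$points
  px <- pts[, 2] + pts[, 3] / 2
  py <- pts[, 3] * sqrt(3) / 2
  op <- graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  for (Y in 1:2) {
    strong <- x$policy[n, , Y] == 2L
    graphics::plot(px, py, pch = 16, cex = 0.4,
                   col = ifelse(strong, "black", "grey80"),
                   xlab = "", ylab = "", axes = FALSE,
                   main = sprintf("n = %d, Y = %s", n, ATTN[Y]), ...)
    graphics::text(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2) + c(-0.03, -0.03, 0.04),
                   STAGES)
  }
  invisible(x)
}

#' Simulate trials from a solved policy
#'
#' @param object A \code{"sat_solution"}.
#' @param nsim Number of trials.
#' @param seed Root seed for the per-trial substreams.
#' @param ... Passed to \code{\link{run_trials}} (e.g. \code{gen_params},
#'   \code{start_Y}).
#' @return A \code{"sat_trials"} object.
#' @export
simulate.sat_solution <- function(object, nsim = 10000, seed = 1L, ...) {
  run_trials(object, n_trials = nsim, seed = seed, ...)
}

#' Export a solution's value/policy tables as CSV
#'
#' One row per (step, grid point, attentional state) with the belief
#' coordinates, value and chosen action: the raw data behind the
#' policy-simplex figures.
#'
#' @param solution A \code{"sat_solution"}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
export_solution_csv <- function(solution, path) {
  P <- nrow(solution$grid$points)
  N <- solution$params$N
  rows <- expand.grid(id = seq_len(P), Y = 1:2, n = seq_len(N))
  df <- data.frame(b_pre = solution$grid$points[rows$id, 1],
                   b_on = solution$grid$points[rows$id, 2],
                   b_post = solution$grid$points[rows$id, 3],
                   Y = ATTN[rows$Y], n = rows$n,
                   value = solution$values[cbind(rows$n, rows$id, rows$Y)],
                   action = ATTN[solution$policy[cbind(rows$n, rows$id, rows$Y)]])
  write_csv17(df, path)
  invisible(path)
}
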