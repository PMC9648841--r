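# Fixed orderings used by every vector/matrix in the package.
STAGES <- c("pre", "on", "post")
ATTN <- c("weak", "strong")
REPORTS <- c("no_signal", "signal")

stage_index <- function(x) {
  i <- match(x, STAGES)
  if (anyNA(i)) stop("unknown stage label; must be one of pre/on/post")
  i
}

attn_index <- function(a) {
  i <- match(a, ATTN)
  if (anyNA(i)) stop("unknown attention label; must be weak or strong")
  i
}

#' External (trial-stage) transition matrix
#'
#' Row-stochastic matrix \code{P(X[n+1] | X[n])} over (pre, on, post).  The
#' pre row moves to on with the arrival hazard of step \code{n + 1}; the on
#' row moves to post with the offset probability \code{q}; post is absorbing.
#' At \code{n = N - 1} any signal still on is transferred to post with
#' certainty so that the decision step only distinguishes "no signal so far"
#' from "signal occurred".
#'
#' @param n Step index, \code{1 <= n <= N - 1}.
#' @param params A \code{\link{task_params}} object.
#' @return A 3x3 row-stochastic matrix with dimnames (pre, on, post).
#' @export
external_transition <- function(n, params) {
  if (n < 1L || n > params$N - 1L)
    stop("external_transition is defined for 1 <= n <= N - 1")
  lam <- hazard(n + 1L, params)
  q_off <- if (n == params$N - 1L) 1 else params$q
  m <- matrix(c(1 - lam, lam,       0,
                0,       1 - q_off, q_off,
                0,       0,         1),
              3, 3, byrow = TRUE, dimnames = list(STAGES, STAGES))
  m
}

#' Internal (attentional) transition matrix
#'
#' Within a trial the next attentional state is exactly the chosen action;
#' the full state transition is the Kronecker product of
#' \code{\link{external_transition}} with this matrix.
#'
#' @param a Attentional action, \code{"weak"} or \code{"strong"}.
#' @return A 2x2 row-stochastic matrix \code{P(Y[n+1] | a[n])}.
#' @export
internal_transition <- function(a) {
  j <- attn_index(a)
  m <- matrix(0, 2, 2, dimnames = list(ATTN, ATTN))
  m[, j] <- 1
  m
}

#' Observation density
#'
#' Observations are Gaussian with mean 1 while the signal is on and mean 0
#' otherwise; the standard deviation is \code{sigma_w} under weak and
#' \code{sigma_s} under strong attention (noise does not depend on signal
#' presence).  No observation is emitted at the decision step.
#'
#' @param o Observation value(s).
#' @param x Stage label ("pre", "on", "post").
#' @param a Attentional action ("weak", "strong").
#' @param params A \code{\link{task_params}} object.
#' @return Density value(s).
#' @export
observation_density <- function(o, x, a, params) {
  mu <- c(0, 1, 0)[stage_index(x)]
  sd <- c(params$sigma_w, params$sigma_s)[attn_index(a)]
  stats::dnorm(o, mean = mu, sd = sd)
}

#' Internal attentional cost
#'
#' Zero for a weak action; \code{epsilon} for maintaining strong attention;
#' \code{kappa} for a weak-to-strong switch.  Both costs are <= 0 and
#' switching is at least as costly as maintaining.
#'
#' @param Y Current attentional state ("weak"/"strong").
#' @param a Attentional action.
#' @param params A \code{\link{task_params}} object.
#' @return A non-positive reward.
#' @export
internal_cost <- function(Y, a, params) {
  yi <- attn_index(Y); ai <- attn_index(a)
  ifelse(ai == 1L, 0, ifelse(yi == 2L, params$epsilon, params$kappa))
}

# internal cost table indexed [Y, a]: weak actions are free; strong costs
# kappa from weak (switch) and epsilon from strong (maintenance)
cost_table <- function(params) {
  matrix(c(0, 0, params$kappa, params$epsilon), 2, 2,
         dimnames = list(ATTN, ATTN))
}

#' External reward of the trial report
#'
#' One unit of reward for a correct report: "no_signal" is correct when the
#' penultimate stage is pre; "signal" is correct when it is on or post.
#'
#' @param x_penult Realized stage at step \code{N - 1}.
#' @param report \code{"no_signal"} or \code{"signal"}.
#' @return 0 or 1.
#' @export
external_reward <- function(x_penult, report) {
  xi <- stage_index(x_penult)
  ri <- match(report, REPORTS)
  if (anyNA(ri)) stop("report must be 'no_signal' or 'signal'")
  as.numeric((ri == 1L & xi == 1L) | (ri == 2L & xi != 1L))
}
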