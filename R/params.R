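#' Task parameters for the sustained attention task model
#'
#' Bundles every generative, observational and cost parameter of one model
#' configuration.  A trial has \code{N = N0 + N1 + 1} time steps: \code{N0}
#' guaranteed pre-signal steps, \code{N1} steps during which a signal may
#' arrive (uniformly), and a final decision step at which the agent reports
#' whether a signal occurred.  Once on, the signal turns off with probability
#' \code{q} per step and is always off before the decision step.
#'
#' @param p1 Probability that a trial contains a signal (the agent's assumed
#'   value; the generative value may differ in mismatch experiments).
#' @param q Per-step probability that an ongoing signal turns off.
#' @param N0 Number of guaranteed pre-signal steps (>= 1).
#' @param N1 Number of steps in which the signal may arrive (>= 1).
#' @param sigma_w Observation standard deviation under weak attention.
#' @param sigma_s Observation standard deviation under strong attention
#'   (must satisfy \code{0 < sigma_s <= sigma_w}).
#' @param kappa Cost (<= 0) of choosing strong attention while in the weak
#'   attentional state (a weak-to-strong switch).
#' @param epsilon Cost (<= 0) of choosing strong attention while already in
#'   the strong state (maintenance); \code{kappa <= epsilon <= 0}.
#' @param delta Probability that strong attention spontaneously reverts to
#'   weak at a trial boundary.
#'
#' @return An object of class \code{"sat_params"}: a list with the above
#'   fields plus \code{p0 = 1 - p1} and the trial length \code{N}.
#' @examples
#' p <- task_params()
#' p$N  # 10 at the default N0 = 3, N1 = 6
#' @export
task_params <- function(p1 = 0.5, q = 0.2, N0 = 3, N1 = 6,
                        sigma_w = 1, sigma_s = 0.5,
                        kappa = -0.1, epsilon = -0.014, delta = 0.001) {
  params <- list(p1 = p1, p0 = 1 - p1, q = q, N0 = as.integer(N0),
                 N1 = as.integer(N1), N = as.integer(N0 + N1 + 1),
                 sigma_w = sigma_w, sigma_s = sigma_s,
                 kappa = kappa, epsilon = epsilon, delta = delta)
  class(params) <- "sat_params"
  validate_params(params)
  params
}

validate_params <- function(p) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop(sprintf("invalid task parameter '%s': %s", field, msg),
                          call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("p1", "q", "sigma_w", "sigma_s", "kappa", "epsilon", "delta"))
    chk(num1(p[[f]]), f, "must be a single finite number")
  chk(p$p1 >= 0 && p$p1 <= 1, "p1", "must lie in [0, 1]")
  chk(p$q >= 0 && p$q <= 1, "q", "must lie in [0, 1]")
  chk(p$delta >= 0 && p$delta <= 1, "delta", "must lie in [0, 1]")
  chk(p$N0 >= 1, "N0", "must be >= 1")
  chk(p$N1 >= 1, "N1", "must be >= 1")
  chk(p$N == p$N0 + p$N1 + 1L, "N", "must equal N0 + N1 + 1")
  chk(p$sigma_s > 0, "sigma_s", "must be > 0")
  chk(p$sigma_s <= p$sigma_w, "sigma_s", "must be <= sigma_w")
  chk(p$kappa <= 0, "kappa", "must be <= 0")
  chk(p$epsilon <= 0, "epsilon", "must be <= 0")
  chk(p$kappa <= p$epsilon, "kappa", "must be <= epsilon (switching at least as costly)")
  invisible(p)
}

#' @export
print.sat_params <- function(x, ...) {
  cat("SAT task parameters\n")
  cat(sprintf("  trial: N0 = %d pre-signal, N1 = %d arrival steps, N = %d total\n",
              x$N0, x$N1, x$N))
  cat(sprintf("  signal: p1 = %g, offset q = %g\n", x$p1, x$q))
  cat(sprintf("  observation SD: weak %g, strong %g\n", x$sigma_w, x$sigma_s))
  cat(sprintf("  costs: switch kappa = %g, maintain epsilon = %g\n",
              x$kappa, x$epsilon))
  cat(sprintf("  boundary decay delta = %g\n", x$delta))
  invisible(x)
}

.config_keys <- c("p1", "q", "N0", "N1", "sigma_w", "sigma_s",
                  "kappa", "epsilon", "delta")

#' Read task parameters from a flat key:value config file
#'
#' The file is a flat YAML mapping whose permitted keys are exactly
#' \code{p1, q, N0, N1, sigma_w, sigma_s, kappa, epsilon, delta}.  Missing
#' keys take the package defaults (the frequent-signal regime); unknown keys
#' are an error.
#'
#' @param path Path to the config file.  An empty file yields the defaults.
#' @return A \code{\link{task_params}} object.
#' @export
read_task_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("malformed config: expected flat key: value mapping")
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(task_params, cfg)
}

#' Write task parameters to a flat key:value config file
#'
#' @param params A \code{\link{task_params}} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_task_config <- function(params, path) {
  stopifnot(inherits(params, "sat_params"))
  lines <- vapply(.config_keys, function(k)
    sprintf("%s: %.17g", k, as.numeric(params[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}
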