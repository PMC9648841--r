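.sweep_params <- c("p1", "q", "sigma_s", "kappa", "epsilon")

#' Sweep one model parameter
#'
#' Re-solves the model at each value of one parameter, holding the others at
#' their configured values, and records the policy statistics computed by
#' exact forward propagation: expected strong-attention steps per trial,
#' per-step probability of the strong action, hit and false-alarm rates, d',
#' and the reward rate; optionally the same for the always-weak and
#' always-strong reference policies.
#'
#' In \code{"single"} (episodic) mode each trial is solved and executed in
#' isolation, starting in the weak attentional state; this exposes the
#' within-trial engagement structure and its breaking points.  In
#' \code{"average"} mode the continuing problem is solved and occupancy is
#' measured at the stationary cross-trial attentional distribution; because
#' the boundary decay \code{delta} is small, the strong state is nearly
#' absorbing there and occupancy is dominated by cross-trial maintenance.
#'
#' @param param_name One of \code{"p1"}, \code{"q"}, \code{"sigma_s"},
#'   \code{"kappa"}, \code{"epsilon"} (costs on their natural, signed scale).
#' @param values Parameter values.
#' @param params Base configuration (defaults: the frequent-signal regime).
#' @param mode \code{"single"} (default) or \code{"average"}.
#' @param grid,quad Discretization (quadrature rebuilt per value when NULL).
#' @param include_baselines Also evaluate the two fixed policies.
#' @param verbose Print one progress line per value.
#' @return A \code{"sat_sweep"}: list with \code{table} (one row per value)
#'   and \code{p_strong} (values x N matrix of per-step strong probability
#'   under the optimal policy).
#' @export
sweep_parameter <- function(param_name, values, params = task_params(),
                            mode = c("single", "average"),
                            grid = make_grid(), quad = NULL,
                            include_baselines = TRUE, verbose = FALSE) {
  mode <- match.arg(mode)
  if (!param_name %in% .sweep_params)
    stop("param_name must be one of: ", paste(.sweep_params, collapse = ", "))
  start <- if (mode == "single") "weak" else "stationary"
  rows <- vector("list", length(values))
  p_strong <- NULL
  for (k in seq_along(values)) {
    override <- stats::setNames(list(values[k]), param_name)
    pk <- do.call(task_params, utils::modifyList(params[.config_keys], override))
    qk <- if (is.null(quad)) make_quadrature(pk) else quad
    sol <- if (mode == "single") solve_single_trial(pk, grid, qk)
           else solve_average_reward(pk, grid, qk)
    st <- policy_stats(sol, start = start)
    if (is.null(p_strong)) p_strong <- matrix(0, length(values), pk$N)
    p_strong[k, ] <- st$p_strong
    row <- data.frame(value = values[k], strong_steps = st$strong_steps,
                      H = st$H, F = st$F, d_prime = st$d_prime,
                      reward_rate = st$reward_rate,
                      g_star = if (is.null(sol$g_star)) NA_real_ else sol$g_star)
    if (include_baselines) {
      for (kind in c("always_weak", "always_strong")) {
        fp <- fixed_policy(kind, pk, grid, qk)
        fs <- policy_stats(fp, start = start)
        suff <- if (kind == "always_weak") "weak" else "strong"
        row[[paste0("H_", suff)]] <- fs$H
        row[[paste0("F_", suff)]] <- fs$F
        row[[paste0("d_prime_", suff)]] <- fs$d_prime
        row[[paste0("reward_rate_", suff)]] <- fs$reward_rate
        row[[paste0("g_star_", suff)]] <- fp$g_star
      }
    }
    rows[[k]] <- row
    if (verbose)
      message(sprintf("sweep %s = %g: strong steps %.4f, reward rate %.5f",
                      param_name, values[k], st$strong_steps, st$reward_rate))
  }
  structure(list(param = param_name, mode = mode,
                 table = do.call(rbind, rows), p_strong = p_strong),
            class = "sat_sweep")
}

#' @export
print.sat_sweep <- function(x, ...) {
  cat(sprintf("parameter sweep over %s (%d values, %s mode)\n", x$param,
              nrow(x$table), x$mode))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

# Occupancy below this is treated as "strong attention never engaged" when
# locating a breaking point (well below one step in a million trials).
.zero_occupancy <- 1e-6

#' Breaking point of a sweep
#'
#' Smallest swept value from which the expected number of strong-attention
#' steps per trial is (and remains) zero, scanning in the order the values
#' were swept.
#'
#' @param sweep A \code{"sat_sweep"} object.
#' @param tol Occupancy below which strong attention counts as never engaged.
#' @return The breaking-point value, or NA if strong attention is engaged at
#'   every swept value.
#' @export
breaking_point <- function(sweep, tol = .zero_occupancy) {
  zero <- sweep$table$strong_steps < tol
  onward <- rev(cumprod(rev(zero))) > 0
  if (!any(onward)) return(NA_real_)
  sweep$table$value[which(onward)[1]]
}
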