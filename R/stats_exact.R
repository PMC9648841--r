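# Exact (grid-resolution) forward statistics of a solved policy.
#
# Propagates the joint distribution over (grid belief, latent stage X,
# current attentional state Y) through the trial, marginalizing observations
# over the quadrature.  Belief updates use the solution's believed model;
# observation frequencies use the generative parameters (identical in
# matched runs).  Both possible start attentional states are propagated at
# once, and combined under the stationary distribution of the cross-trial
# attentional chain the policy induces.

#' Exact performance statistics of a solved policy
#'
#' Computes, without Monte-Carlo error (at the grid/quadrature resolution),
#' the per-step probability of choosing strong attention, the expected number
#' of strong-attention steps per trial, hit and false-alarm rates, the
#' sensitivity d', and the reward rate per step under the given policy.
#'
#' @param solution A \code{"sat_solution"}.
#' @param gen_params Generative parameters (defaults to the believed ones).
#' @param start Start attentional state: \code{"stationary"} (default; the
#'   stationary mix of the policy's own cross-trial chain), \code{"weak"} or
#'   \code{"strong"}.
#' @param rate_floor Floor applied to exact hit/false-alarm rates before the
#'   quantile transform, mirroring the 1/(2m) correction at m = 5000 trials
#'   per type.
#' @return List with \code{H}, \code{F}, \code{d_prime},
#'   \code{strong_steps}, \code{p_strong} (length-N vector),
#'   \code{reward_rate}, \code{start_strong} (stationary probability of
#'   starting a trial with strong attention), \code{next_Y} (2x2 cross-trial
#'   transition matrix) and \code{by_start} (per-start-state breakdown).
#' @export
policy_stats <- function(solution, gen_params = solution$params,
                         start = c("stationary", "weak", "strong"),
                         rate_floor = 1e-4) {
  start <- match.arg(start)
  params <- solution$params
  grid <- solution$grid
  quad <- solution$quad
  N <- params$N
  P <- nrow(grid$points)
  pol <- solution$policy
  costs <- cost_table(params)
  mu <- c(0, 1, 0)
  sig_gen <- c(gen_params$sigma_w, gen_params$sigma_s)
  no <- length(quad$nodes)

  # J[[Ycur]]: P x 6 matrix; columns are stage X (1..3) within start state
  # (weak block cols 1:3, strong block cols 4:6)
  id0 <- grid_origin_id(grid)
  J <- list(matrix(0, P, 6), matrix(0, P, 6))
  J[[1]][id0, 1] <- 1  # start weak
  J[[2]][id0, 4] <- 1  # start strong
  p_strong <- matrix(0, N, 2)           # per step, per start state
  cost_acc <- c(0, 0)                   # internal cost per trial, per start

  for (n in seq_len(N - 1L)) {
    Tn <- external_transition(n, params)
    Tn_gen <- external_transition(n, gen_params)
    strong_rows <- list(pol[n, , 1] == 2L, pol[n, , 2] == 2L)
    for (Y in 1:2) {
      m_strong <- colSums(J[[Y]][strong_rows[[Y]], , drop = FALSE])
      by_start <- c(sum(m_strong[1:3]), sum(m_strong[4:6]))
      p_strong[n, ] <- p_strong[n, ] + by_start
      cost_acc <- cost_acc + by_start * costs[Y, 2]
    }
    newJ <- list(matrix(0, P, 6), matrix(0, P, 6))
    for (a in 1:2) {
      # mass taking action a, merged over current Y (successor Y is a)
      Min <- matrix(0, P, 6)
      for (Y in 1:2) {
        rows <- pol[n, , Y] == a
        Min[rows, ] <- Min[rows, ] + J[[Y]][rows, ]
      }
      if (sum(Min) < 1e-300) next
      # believed update scatter, weighted by generative observation mass
      ii <- vector("list", no); jj <- vector("list", no)
      x1 <- vector("list", no); x2 <- vector("list", no); x3 <- vector("list", no)
      wX <- outer(quad$weights, numeric(3), `+`)
      for (X in 1:3)
        wX[, X] <- stats::dnorm(quad$nodes, mu[X], sig_gen[a]) * quad$weights
      wX <- sweep(wX, 2, colSums(wX), "/")  # mass-conserving per stage
      rows_all <- seq_len(P)
      for (k in seq_len(no)) {
        up <- update_batch(grid$points, ATTN[a], quad$nodes[k], n, params, Tn)
        loc <- locate_simplex(grid, up$beliefs)
        ii[[k]] <- rep(rows_all, 3)
        jj[[k]] <- as.vector(loc$ids)
        x1[[k]] <- as.vector(loc$w) * wX[k, 1]
        x2[[k]] <- as.vector(loc$w) * wX[k, 2]
        x3[[k]] <- as.vector(loc$w) * wX[k, 3]
      }
      i_all <- unlist(ii); j_all <- unlist(jj)
      out <- matrix(0, P, 6)
      for (X in 1:3) {
        S <- Matrix::sparseMatrix(i = i_all, j = j_all,
                                  x = unlist(list(x1, x2, x3)[[X]]),
                                  dims = c(P, P))
        cols <- c(X, X + 3L)
        out[, cols] <- as.matrix(Matrix::crossprod(S, Min[, cols]))
      }
      # latent stage transition (generative), per start block
      out[, 1:3] <- out[, 1:3] %*% Tn_gen
      out[, 4:6] <- out[, 4:6] %*% Tn_gen
      newJ[[a]] <- out
    }
    J <- newJ
  }

  # decision step: attentional action, report, outcome, cross-trial Y
  rep_sig <- solution$report_signal
  ext_rew <- c(0, 0)
  hitmass <- c(0, 0); sigmass <- c(0, 0)
  famass <- c(0, 0); nonmass <- c(0, 0)
  next_strong <- c(0, 0)
  for (Y in 1:2) {
    strong_rows <- pol[N, , Y] == 2L
    m_strong <- colSums(J[[Y]][strong_rows, , drop = FALSE])
    by_start_strong <- c(sum(m_strong[1:3]), sum(m_strong[4:6]))
    p_strong[N, ] <- p_strong[N, ] + by_start_strong
    cost_acc <- cost_acc + by_start_strong * costs[Y, 2]
    next_strong <- next_strong + by_start_strong * (1 - params$delta)
    for (s in 1:2) {
      blk <- J[[Y]][, (s - 1L) * 3L + (1:3), drop = FALSE]
      post <- blk[, 2] + blk[, 3]   # signal occurred (on already forced to post)
      pre <- blk[, 1]
      sigmass[s] <- sigmass[s] + sum(post)
      nonmass[s] <- nonmass[s] + sum(pre)
      hitmass[s] <- hitmass[s] + sum(post[rep_sig])
      famass[s] <- famass[s] + sum(pre[rep_sig])
      ext_rew[s] <- ext_rew[s] + sum(pre[!rep_sig]) + sum(post[rep_sig])
    }
  }
  A_gen <- cbind(1 - next_strong, next_strong)  # rows: start Y; cols: next Y

  start_dist <- switch(start,
    weak = c(1, 0),
    strong = c(0, 1),
    stationary = {
      denom <- 1 - A_gen[2, 2] + A_gen[1, 2]
      ps <- if (denom < 1e-14) 0 else A_gen[1, 2] / denom
      c(1 - ps, ps)
    })

  mix <- function(x) sum(x * start_dist)
  H <- mix(hitmass) / max(mix(sigmass), 1e-300)
  F <- mix(famass) / max(mix(nonmass), 1e-300)
  Hc <- min(max(H, rate_floor), 1 - rate_floor)
  Fc <- min(max(F, rate_floor), 1 - rate_floor)
  strong_steps <- colSums(p_strong)
  reward <- ext_rew + cost_acc
  list(H = H, F = F, d_prime = stats::qnorm(Hc) - stats::qnorm(Fc),
       strong_steps = mix(strong_steps),
       p_strong = as.numeric(p_strong %*% start_dist),
       reward_rate = mix(reward) / N,
       start_strong = start_dist[2], next_Y = A_gen,
       by_start = list(strong_steps = strong_steps,
                       reward = reward, H = hitmass / pmax(sigmass, 1e-300),
                       F = famass / pmax(nonmass, 1e-300)))
}
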