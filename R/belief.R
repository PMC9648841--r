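#' Regular belief-simplex grid
#'
#' All beliefs over (pre, on, post) whose coordinates are multiples of
#' \code{delta_b}.  With \code{M = 1/delta_b} the grid has
#' \code{(M+1)(M+2)/2} points, including the three vertices.
#'
#' @param delta_b Tile side; \code{1/delta_b} must be an integer.
#' @return Object of class \code{"sat_grid"}: list with \code{delta_b},
#'   \code{M}, \code{points} (P x 3 matrix, columns pre/on/post) and an
#'   internal index map.
#' @export
make_grid <- function(delta_b = 0.02) {
  M <- 1 / delta_b
  if (abs(M - round(M)) > 1e-9) stop("1/delta_b must be an integer")
  M <- as.integer(round(M))
  i <- unlist(lapply(0:M, function(ii) rep(ii, M - ii + 1L)))
  j <- unlist(lapply(0:M, function(ii) 0:(M - ii)))
  k <- M - i - j
  points <- cbind(pre = i, on = j, post = k) / M
  lookup <- matrix(NA_integer_, M + 1L, M + 1L)
  lookup[cbind(i + 1L, j + 1L)] <- seq_along(i)
  structure(list(delta_b = delta_b, M = M, points = points, lookup = lookup),
            class = "sat_grid")
}

#' @export
print.sat_grid <- function(x, ...) {
  cat(sprintf("belief simplex grid: delta_b = %g, %d points\n",
              x$delta_b, nrow(x$points)))
  invisible(x)
}

# Locate beliefs in the simplex lattice.  B is an m x 3 matrix of beliefs
# (rows sum to 1).  Returns the ids of the three corners of the containing
# lattice triangle and the barycentric weights; exact grid points get weight
# 1 on themselves.  Vectorized over rows.
locate_simplex <- function(grid, B) {
  M <- grid$M
  U <- B * M
  F0 <- floor(U + 1e-12)
  F0 <- pmin(pmax(F0, 0), M)
  r <- U - F0
  s <- round(rowSums(r))
  # s == 3 means U was (essentially) the lattice point F0 + 1
  up3 <- s == 3
  if (any(up3)) {
    F0[up3, ] <- F0[up3, ] + 1
    r[up3, ] <- 0
    s[up3] <- 0
  }
  m <- nrow(B)
  ids <- matrix(1L, m, 3)
  w <- matrix(0, m, 3)
  id_of <- function(fi, fj) grid$lookup[cbind(as.integer(fi) + 1L,
                                              as.integer(fj) + 1L)]
  e <- diag(3)
  s0 <- s == 0
  if (any(s0)) {
    ids[s0, 1] <- id_of(F0[s0, 1], F0[s0, 2])
    ids[s0, 2] <- ids[s0, 1]; ids[s0, 3] <- ids[s0, 1]
    w[s0, 1] <- 1
  }
  s1 <- s == 1
  if (any(s1)) {
    for (kk in 1:3)
      ids[s1, kk] <- id_of(F0[s1, 1] + e[1, kk], F0[s1, 2] + e[2, kk])
    w[s1, ] <- r[s1, , drop = FALSE]
  }
  s2 <- s == 2
  if (any(s2)) {
    for (kk in 1:3)
      ids[s2, kk] <- id_of(F0[s2, 1] + 1 - e[1, kk], F0[s2, 2] + 1 - e[2, kk])
    w[s2, ] <- 1 - r[s2, , drop = FALSE]
  }
  # floating-point hygiene
  w[w < 0] <- 0
  w <- w / rowSums(w)
  if (anyNA(ids)) stop("belief outside the simplex lattice")
  list(ids = ids, w = w)
}

#' Barycentric interpolation of a per-grid-point table
#'
#' Interpolates within the lattice triangle containing each query belief.
#' Exact at grid points; reproduces affine functions of the belief exactly;
#' always a convex combination of the three corner values.
#'
#' @param grid A \code{\link{make_grid}} object.
#' @param table Numeric vector with one value per grid point.
#' @param b A belief (length-3 vector) or an m x 3 matrix of beliefs.
#' @return Interpolated value(s).
#' @export
interpolate_grid <- function(grid, table, b) {
  B <- if (is.matrix(b)) b else matrix(b, 1, 3)
  loc <- locate_simplex(grid, B)
  vals <- matrix(table[loc$ids], nrow(B), 3)
  rowSums(vals * loc$w)
}

#' Nearest grid point
#'
#' The corner of the containing lattice triangle with the largest barycentric
#' weight.  Used for discrete action lookup during simulation (actions are
#' categorical, so they are read at the nearest grid point rather than
#' interpolated).
#'
#' @inheritParams interpolate_grid
#' @return Integer grid id(s).
#' @export
nearest_grid_point <- function(grid, b) {
  B <- if (is.matrix(b)) b else matrix(b, 1, 3)
  loc <- locate_simplex(grid, B)
  loc$ids[cbind(seq_len(nrow(B)), max.col(loc$w, ties.method = "first"))]
}

#' Bayesian belief update
#'
#' One filtering step: the step-\code{n} likelihood of the observation is
#' applied to the current belief, which is then pushed through the
#' \code{n -> n+1} stage transition and renormalized,
#' \deqn{b_{n+1}(x) \propto \sum_\chi P(X_{n+1}=x | X_n=\chi)\,
#'   P(o | X_n=\chi, a)\, b_n(\chi).}
#'
#' @param b Current belief (length-3, sums to 1).
#' @param a Attentional action in force at step \code{n}.
#' @param o Observation at step \code{n}.
#' @param n Step index, \code{1 <= n <= N - 1}.
#' @param params A \code{\link{task_params}} object.
#' @return List with \code{belief} (the updated length-3 belief) and
#'   \code{evidence} (the normalizing constant \code{P(o | a, b)}).
#' @export
belief_update <- function(b, a, o, n, params) {
  lik <- observation_density(o, STAGES, a, params)
  v <- b * lik
  ev <- sum(v)
  if (ev <= 0) stop("zero evidence in belief update")
  bn <- as.numeric(v %*% external_transition(n, params)) / ev
  bn[bn < 1e-15] <- 0
  bn <- bn / sum(bn)
  list(belief = bn, evidence = ev)
}

#' Observation quadrature
#'
#' Uniform trapezoid rule on \code{[-5 sigma_w, 1 + 5 sigma_w]}, the interval
#' carrying essentially all observation mass under either attentional state.
#' Evidence weights are renormalized per belief when marginalizing, so small
#' truncation mass is redistributed proportionally.
#'
#' @param params A \code{\link{task_params}} object.
#' @param n_nodes Number of quadrature nodes (default 201).
#' @return List with \code{nodes} and \code{weights}.
#' @export
make_quadrature <- function(params, n_nodes = 201) {
  if (n_nodes < 2) stop("quadrature needs at least 2 nodes")
  lo <- -5 * params$sigma_w
  hi <- 1 + 5 * params$sigma_w
  nodes <- seq(lo, hi, length.out = n_nodes)
  h <- (hi - lo) / (n_nodes - 1)
  weights <- rep(h, n_nodes)
  weights[c(1, n_nodes)] <- h / 2
  list(nodes = nodes, weights = weights)
}

# Batched belief update for all rows of B (m x 3) at a single observation o.
# Returns the updated beliefs (m x 3), the evidence vector (length m), and
# optionally their lattice location.
update_batch <- function(B, a, o, n, params, Tn = external_transition(n, params)) {
  lik <- observation_density(o, STAGES, a, params)
  V <- B %*% diag(lik)
  ev <- rowSums(V)
  Bn <- (V %*% Tn) / ev
  list(beliefs = Bn, evidence = ev)
}

#' Discretized belief transition operator
#'
#' The grid version of the belief-MDP transition function: observations are
#' marginalized over the quadrature, each updated belief scatters its
#' evidence mass onto the corners of the containing lattice triangle by
#' barycentric weights, and rows are renormalized to sum to one.
#'
#' @param n Step index, \code{1 <= n <= N - 1}.
#' @param a Attentional action ("weak"/"strong").
#' @param grid A \code{\link{make_grid}} object.
#' @param params A \code{\link{task_params}} object.
#' @param quad A \code{\link{make_quadrature}} spec.
#' @return Sparse row-stochastic \code{P x P} matrix (class dgCMatrix) whose
#'   (i, j) entry is the probability of moving from grid belief i to grid
#'   belief j under action \code{a} at step \code{n}.
#' @export
belief_transition_matrix <- function(n, a, grid, params, quad) {
  if (length(quad$nodes) == 0) stop("empty quadrature")
  P <- nrow(grid$points)
  Tn <- external_transition(n, params)
  no <- length(quad$nodes)
  ii <- vector("list", no); jj <- vector("list", no); xx <- vector("list", no)
  rows <- seq_len(P)
  for (k in seq_len(no)) {
    up <- update_batch(grid$points, a, quad$nodes[k], n, params, Tn)
    loc <- locate_simplex(grid, up$beliefs)
    mass <- up$evidence * quad$weights[k]
    ii[[k]] <- rep(rows, 3)
    jj[[k]] <- as.vector(loc$ids)
    xx[[k]] <- as.vector(loc$w) * rep(mass, 3)
  }
  Phi <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(P, P))
  Matrix::Diagonal(x = 1 / Matrix::rowSums(Phi)) %*% Phi
}

# All transition operators of a configuration: list indexed [[n]][[a]].
transition_operators <- function(grid, params, quad) {
  lapply(seq_len(params$N - 1L), function(n)
    lapply(1:2, function(ai)
      belief_transition_matrix(n, ATTN[ai], grid, params, quad)))
}

#' Expected one-step reward in the belief MDP
#'
#' For \code{n < N} this is the attentional cost, independent of the belief;
#' at \code{n = N} it adds the expected external reward of the report under
#' the belief.
#'
#' @param b Belief (length-3).
#' @param Y Current attentional state.
#' @param a Attentional action.
#' @param n Step index.
#' @param params A \code{\link{task_params}} object.
#' @param report At \code{n = N}, \code{"no_signal"} or \code{"signal"}.
#' @return Expected reward.
#' @export
belief_reward <- function(b, Y, a, n, params, report = NULL) {
  r <- internal_cost(Y, a, params)
  if (n == params$N) {
    if (is.null(report)) stop("a report is required at n = N")
    ri <- match(report, REPORTS)
    r <- r + if (ri == 1L) b[1] else b[2] + b[3]
  }
  r
}
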