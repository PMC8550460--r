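# Competitive swarm optimizer: randomly paired particles compete, the
# loser of each pair moves toward the winner (and optionally the swarm
# center), the winner is left alone.

#' Tuning parameters for the competitive swarm optimizer
#'
#' Defaults follow the tuning used throughout the design searches:
#' \eqn{\gamma = 0} (no center attraction) with 128 particles and at most
#' 350 iterations, declaring convergence when the best objective value
#' changes by less than `tol = 1e-6` over `stall_iter` consecutive
#' iterations.
#'
#' @param swarm Even swarm size, at least 4.
#' @param max_iter Maximum number of iterations.
#' @param gamma Social factor controlling attraction of losers toward
#'   the swarm center; larger values add diversity.
#' @param tol Convergence tolerance on the change of the best value.
#' @param stall_iter Consecutive near-stationary iterations required to
#'   stop early.
#' @param seed Optional integer seed.  When `NULL` the current RNG
#'   stream is used, which is what nested searches should do so that one
#'   top-level seed governs the whole run.
#' @param velocity_init `"zero"` (default, reproducible) or `"uniform"`
#'   for random initial velocities.
#' @return A `cso_config` list.
#' @export
cso_config <- function(swarm = 128L, max_iter = 350L, gamma = 0,
                       tol = 1e-6, stall_iter = 50L, seed = NULL,
                       velocity_init = c("zero", "uniform")) {
  swarm <- as.integer(swarm)
  if (swarm < 4L || swarm %% 2L != 0L) {
    stop("`swarm` must be an even integer of at least 4.")
  }
  if (tol <= 0) stop("`tol` must be positive.")
  if (gamma < 0) stop("`gamma` must be nonnegative.")
  structure(list(swarm = swarm, max_iter = as.integer(max_iter),
                 gamma = gamma, tol = tol,
                 stall_iter = as.integer(stall_iter), seed = seed,
                 velocity_init = match.arg(velocity_init)),
            class = "cso_config")
}

#' Pairwise competition update
#'
#' The loser's velocity is refreshed as
#' \eqn{v \leftarrow R_1 \circ v + R_2 \circ (x_{win} - x_{lose}) +
#' \gamma R_3 \circ (\bar x - x_{lose})} with fresh `U(0,1)` vectors
#' \eqn{R_1, R_2, R_3}, its position moves by the new velocity and is
#' clipped to the bounds (clipped components get zero velocity).  The
#' winner is returned unchanged.
#'
#' @param winner,loser Lists with `position` and `velocity` vectors; the
#'   winner is the pair member with the smaller objective value.
#' @param center Current swarm center (mean position).
#' @param lower,upper Box bounds.
#' @param gamma Social factor.
#' @return The updated loser (list with `position`, `velocity`).
#' @export
compete_and_update <- function(winner, loser, center, lower, upper,
                               gamma = 0) {
  d <- length(loser$position)
  R1 <- stats::runif(d); R2 <- stats::runif(d); R3 <- stats::runif(d)
  v <- R1 * loser$velocity + R2 * (winner$position - loser$position) +
    gamma * R3 * (center - loser$position)
  x <- loser$position + v
  out <- x < lower | x > upper
  x <- pmin(pmax(x, lower), upper)
  v[out] <- 0
  list(position = x, velocity = v)
}

#' Minimize a function with the competitive swarm optimizer
#'
#' @param fn Objective returning a scalar; non-finite values are treated
#'   as `+Inf` (the particle loses its competitions).
#' @param lower,upper Box bounds (numeric vectors of equal length).
#' @param config A [cso_config()].
#' @return A list: `par`, `value`, `history` (best value per iteration,
#'   nonincreasing), `iterations`, `converged`.
#' @export
#' @examples
#' res <- cso_minimize(function(z) sum((z - 0.3)^2), rep(-5, 3), rep(5, 3),
#'                     cso_config(swarm = 64, max_iter = 150, seed = 1))
#' round(res$par, 3)
cso_minimize <- function(fn, lower, upper, config = cso_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  d <- length(lower)
  stopifnot(length(upper) == d)
  n <- config$swarm
  X <- matrix(stats::runif(n * d, rep(lower, each = n), rep(upper, each = n)),
              n, d)
  V <- if (config$velocity_init == "uniform") {
    span <- upper - lower
    matrix(stats::runif(n * d, rep(-span, each = n), rep(span, each = n)), n, d)
  } else {
    matrix(0, n, d)
  }
  evalf <- function(x) {
    v <- fn(x)
    if (!is.finite(v)) Inf else v
  }
  f <- apply(X, 1, evalf)
  best <- min(f)
  history <- numeric(config$max_iter)
  stall <- 0L
  iter <- 0L
  for (t in seq_len(config$max_iter)) {
    iter <- t
    ord <- sample.int(n)
    center <- colMeans(X)
    for (k in seq(1L, n - 1L, by = 2L)) {
      i <- ord[k]; j <- ord[k + 1L]
      if (f[j] < f[i]) { tmp <- i; i <- j; j <- tmp }
      upd <- compete_and_update(
        list(position = X[i, ], velocity = V[i, ]),
        list(position = X[j, ], velocity = V[j, ]),
        center, lower, upper, config$gamma)
      X[j, ] <- upd$position
      V[j, ] <- upd$velocity
      f[j] <- evalf(X[j, ])
    }
    nb <- min(f)
    if (best - nb < config$tol) stall <- stall + 1L else stall <- 0L
    best <- min(best, nb)
    history[t] <- best
    if (stall >= config$stall_iter) break
  }
  i <- which.min(f)
  list(par = X[i, ], value = f[i], history = history[seq_len(iter)],
       iterations = iter, converged = stall >= config$stall_iter)
}

#' Ridge-regularize a symmetric matrix before inversion
#'
#' Adds `eps` to the diagonal (default `1e-7`), the stabilization used
#' on near-singular information matrices during the swarm search; final
#' certification always uses unregularized matrices.
#'
#' @param M Square symmetric matrix.
#' @param eps Diagonal ridge.
#' @export
regularize <- function(M, eps = 1e-7) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  M + eps * diag(nrow(M))
}
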