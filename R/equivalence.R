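# Equivalence-theorem machinery for G-optimality: answering set, the
# probability measure mu on it, the sensitivity function, and the
# optimality certificate.
#
# The sensitivity function is linear in the weights of mu:
#   s(x; mu) = sum_j wmu_j K(x, a_j) - sum_j wmu_j c_j,
#   K(x, a) = (f(x)' Minv f(a))^2 + (n-1) (f(x)' N f(a))^2,
#   c_j     = f(a_j)' Minv f(a_j) + (n-1) f(a_j)' N M N f(a_j),
# which the mu-search exploits by precomputing K at the support and on
# an evaluation grid.

#' Information matrix of a probability measure on the answering set
#'
#' \eqn{M_A(\mu) = \sum_j w_{\mu j} f(a_j) f(a_j)^T}, the moment matrix
#' of the measure \eqn{\mu} entering the G-optimality equivalence
#' theorem.
#'
#' @param measure A design tibble (points with weights) on the answering
#'   set.
#' @param basis A [regression_basis()].
#' @return A symmetric `p x p` matrix.
#' @export
ma_matrix <- function(measure, basis) {
  check_design(measure)
  Fa <- basis_matrix(basis, design_points(measure))
  sym(crossprod(Fa, measure$weight * Fa))
}

# coefficients of the mu-linear sensitivity at evaluation points X
sens_linear_coeffs <- function(X, A_points, parts, n) {
  Fg <- basis_matrix_raw(X, parts)
  Fa <- basis_matrix_raw(A_points, parts)
  K <- (Fg %*% parts$Minv %*% t(Fa))^2 +
    (n - 1) * (Fg %*% parts$N %*% t(Fa))^2
  NMN <- parts$N %*% parts$M %*% parts$N
  cj <- rowSums((Fa %*% parts$Minv) * Fa) + (n - 1) * rowSums((Fa %*% NMN) * Fa)
  sweep(K, 2, cj)            # rows: eval points, cols: answering points
}

# crit_parts carries no basis; stash it for reuse
crit_parts_full <- function(design, model, reg = 0) {
  parts <- crit_parts(design, model, reg = reg)
  parts$basis <- model$basis
  parts
}

basis_matrix_raw <- function(X, parts) {
  basis_matrix(parts$basis, X)
}

#' Sensitivity function of the G-optimality equivalence theorem
#'
#' \eqn{\phi_G(x, \xi) - \mathrm{tr}\{M_A(\mu) M^{-1}(\xi) + (n-1)
#' M(\xi) N M_A(\mu) N\}} with
#' \eqn{\phi_G = f^T M^{-1} M_A M^{-1} f + (n-1) f^T N M_A N f}.
#' A design is G-optimal iff some probability measure \eqn{\mu} on its
#' answering set makes this nonpositive everywhere on the design space;
#' the support points of the optimal design are then roots.
#'
#' @param design A design tibble.
#' @param model An [hlm_model()].
#' @param measure A probability measure on the answering set (design
#'   tibble).
#' @param x Evaluation point(s).
#' @return Numeric vector of sensitivity values.
#' @export
sensitivity_g <- function(design, model, measure, x) {
  parts <- crit_parts_full(design, model)
  X <- as_points_matrix(x, model$space$dim)
  S <- sens_linear_coeffs(X, design_points(measure), parts, model$n)
  drop(S %*% measure$weight)
}

#' Squared-residual loss of a candidate measure
#'
#' The objective minimized by the measure search: in `"simple"` mode the
#' design-weighted squared sensitivity residuals at the design support
#' points; `"full"` mode adds the squared supremum of the sensitivity
#' over the design space (found by inner maximization).
#'
#' @inheritParams sensitivity_g
#' @param mode `"simple"` or `"full"`.
#' @param grid_n Resolution of the inner maximization in full mode.
#' @return A nonnegative scalar.
#' @export
measure_loss <- function(design, model, measure, mode = c("simple", "full"),
                         grid_n = 501) {
  mode <- match.arg(mode)
  resid <- sensitivity_g(design, model, measure, design_points(design))
  loss <- sum(design$weight * resid^2)
  if (mode == "full") {
    parts <- crit_parts_full(design, model)
    fn <- function(X) {
      S <- sens_linear_coeffs(X, design_points(measure), parts, model$n)
      drop(S %*% measure$weight)
    }
    sup <- maximize_over_space(fn, model$space, grid_n = grid_n,
                               polish = FALSE)$value
    loss <- loss + max(sup, 0)^2
  }
  loss
}

#' Locate the answering set of a design
#'
#' The answering set \eqn{A(\xi)} collects every point where the
#' prediction variance \eqn{\phi(\cdot, \xi)} attains its maximum
#' \eqn{\bar\phi(\xi)}.  The design space is split into sub-boxes
#' (starting with `init_splits` per axis), \eqn{\phi} is maximized on
#' each sub-box, and the number of splits doubles until the set size is
#' stable for two consecutive rounds.  Points with
#' \eqn{\phi \ge \bar\phi (1 - eps)} are kept and near-duplicates
#' merged.
#'
#' @inheritParams sensitivity_g
#' @param eps Relative tolerance for membership (default `1e-4`).
#' @param init_splits Initial number of sub-boxes per axis.
#' @param max_splits Cap on splits per axis.
#' @param merge_tol Merge radius for near-duplicate maximizers, in units
#'   of the factor range.
#' @return A tibble of answering-set points (`x1..xd` and their `phi`).
#' @export
answering_set <- function(design, model, eps = 1e-4, init_splits = 2L,
                          max_splits = 32L, merge_tol = 1e-4) {
  parts <- crit_parts_full(design, model)
  fn <- function(X) phi(design, model, X, parts = parts)
  sp <- model$space
  d <- sp$dim
  per_box_grid <- if (d == 1) 201 else if (d == 2) 41 else NULL

  collect <- function(splits) {
    cuts <- lapply(seq_len(d), function(j) {
      seq(sp$lower[j], sp$upper[j], length.out = splits + 1)
    })
    idx <- as.matrix(expand.grid(lapply(seq_len(d), function(j) seq_len(splits))))
    res <- apply(idx, 1, function(ii) {
      lo <- vapply(seq_len(d), function(j) cuts[[j]][ii[j]], 0)
      hi <- vapply(seq_len(d), function(j) cuts[[j]][ii[j] + 1], 0)
      box <- design_space(lo, hi)
      b <- maximize_over_space(fn, box, grid_n = per_box_grid %||% 2001)
      c(b$par, b$value)
    })
    list(points = t(res)[, seq_len(d), drop = FALSE],
         values = t(res)[, d + 1])
  }

  splits <- as.integer(init_splits)
  prev_size <- -1L
  stable <- 0L
  A <- NULL
  repeat {
    got <- collect(splits)
    phi_bar <- max(got$values)
    keep <- got$values >= phi_bar * (1 - eps)
    cand <- design(got$points[keep, , drop = FALSE],
                   rep(1, sum(keep)))
    cand <- normalize_design(cand, space = sp, merge_tol = merge_tol,
                             prune_tol = 0)
    if (nrow(cand) == prev_size) stable <- stable + 1L else stable <- 0L
    prev_size <- nrow(cand)
    A <- cand
    if (stable >= 2L || splits >= max_splits) break
    splits <- splits * 2L
  }
  pts <- design_points(A)
  out <- tibble::as_tibble(as.data.frame(pts))
  names(out) <- paste0("x", seq_len(ncol(pts)))
  out$phi <- fn(pts)
  out
}

#' Find the equivalence-theorem measure on the answering set
#'
#' Searches for the probability measure \eqn{\mu^*} that makes the
#' sensitivity function vanish at the design's support points, by
#' competitive swarm optimization over the weight simplex (raw weights
#' on `[0,1]` normalized to sum 1).  Two stages: first the cheap
#' support-residual loss, then the full loss including the squared
#' supremum term.
#'
#' @inheritParams sensitivity_g
#' @param A Answering set tibble; computed by [answering_set()] when
#'   missing.
#' @param config [cso_config()] for the weight search; default 64
#'   particles, social factor 0.05, up to 1200 iterations.
#' @param stop_loss Loss value considered converged (default `1e-5`).
#' @return The measure as a design tibble with attributes `loss` and
#'   `converged`.
#' @export
find_mu <- function(design, model, A = NULL, config = NULL,
                    stop_loss = 1e-5) {
  if (is.null(A)) A <- answering_set(design, model)
  A_pts <- as_points_matrix(A, model$space$dim)
  kA <- nrow(A_pts)
  if (kA == 1L) {
    out <- design(A_pts, 1)
    attr(out, "loss") <- measure_loss(design, model, out)
    attr(out, "converged") <- TRUE
    return(out)
  }
  parts <- crit_parts_full(design, model)
  S_sup <- sens_linear_coeffs(design_points(design), A_pts, parts, model$n)
  w_des <- design$weight
  simple_loss <- function(r) {
    if (sum(r) <= 0) r <- rep(1, kA)
    wmu <- r / sum(r)
    sum(w_des * drop(S_sup %*% wmu)^2)
  }
  # fixed evaluation set for the supremum term
  sp <- model$space
  if (sp$dim <= 2) {
    ax <- lapply(seq_len(sp$dim), function(j) {
      seq(sp$lower[j], sp$upper[j],
          length.out = if (sp$dim == 1) 501 else 71)
    })
    Xeval <- as.matrix(expand.grid(ax))
  } else {
    Xeval <- matrix(stats::runif(2000 * sp$dim,
                                 rep(sp$lower, each = 2000),
                                 rep(sp$upper, each = 2000)),
                    2000, sp$dim)
  }
  S_grid <- sens_linear_coeffs(Xeval, A_pts, parts, model$n)
  full_loss <- function(r) {
    if (sum(r) <= 0) r <- rep(1, kA)
    wmu <- r / sum(r)
    sum(w_des * drop(S_sup %*% wmu)^2) +
      max(max(drop(S_grid %*% wmu)), 0)^2
  }
  cfg <- config %||% cso_config(swarm = 64L, max_iter = 1200L, gamma = 0.05,
                                stall_iter = 50L)
  st1 <- cso_minimize(simple_loss, rep(0, kA), rep(1, kA), cfg)
  cfg2 <- cfg
  cfg2$max_iter <- min(cfg$max_iter, 300L)
  st2 <- cso_minimize(full_loss, rep(0, kA), rep(1, kA), cfg2)
  cand <- if (full_loss(st1$par) <= full_loss(st2$par)) st1$par else st2$par
  # deterministic local polish
  pol <- tryCatch(
    stats::optim(pmax(cand, 1e-8), full_loss, method = "L-BFGS-B",
                 lower = rep(1e-10, kA), upper = rep(1, kA)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value < full_loss(cand)) cand <- pol$par
  wmu <- cand / sum(cand)
  out <- design(A_pts, wmu)
  attr(out, "loss") <- full_loss(cand)
  attr(out, "converged") <- full_loss(cand) <= stop_loss
  out
}

#' Certify G-optimality of a design
#'
#' Applies the equivalence theorem: finds the answering set, fits the
#' measure \eqn{\mu}, and checks that the sensitivity function is
#' nonpositive over the design space (within `tol` times
#' \eqn{\bar\phi}) and vanishes at the design's support points.
#'
#' @inheritParams sensitivity_g
#' @param tol Relative certification tolerance; the default 0.02 matches
#'   the precision achievable with designs reported to three decimals.
#' @param grid_n Resolution of the final sensitivity sweep.
#' @param mu Optional measure; computed by [find_mu()] when missing.
#' @return An `optimality_report`: answering set, measure, `phi_bar`,
#'   `max_sensitivity` and its location, residuals at support points,
#'   `gap` (G-criterion minus its lower bound), and the `pass` verdict.
#' @export
verify_g_optimality <- function(design, model, tol = 0.02, grid_n = 2001,
                                mu = NULL) {
  check_design(design, model$space)
  A <- answering_set(design, model)
  if (is.null(mu)) mu <- find_mu(design, model, A = A)
  parts <- crit_parts_full(design, model)
  A_mu <- design_points(mu)

  fn <- function(X) {
    S <- sens_linear_coeffs(X, A_mu, parts, model$n)
    drop(S %*% mu$weight)
  }
  sup <- maximize_over_space(fn, model$space, grid_n = grid_n)
  resid <- fn(design_points(design))
  gcrit <- g_criterion(design, model, grid_n = grid_n)
  phi_bar <- gcrit$value
  thresh <- tol * abs(phi_bar)
  pass <- sup$value <= thresh && all(abs(resid) <= thresh)
  structure(
    list(answering_set = A, mu = mu, phi_bar = phi_bar,
         g_lower_bound = g_lower_bound(design, model),
         gap = phi_bar - g_lower_bound(design, model),
         max_sensitivity = sup$value, max_sensitivity_at = sup$par,
         support_residuals = resid, tol = tol, threshold = thresh,
         mu_converged = isTRUE(attr(mu, "converged")),
         pass = pass, design = design),
    class = "optimality_report"
  )
}

#' @export
print.optimality_report <- function(x, ...) {
  cat("<optimality_report> ", if (x$pass) "PASS" else "FAIL",
      " (tol ", format(x$tol), " x phi_bar)\n", sep = "")
  cat("  phi_bar = ", format(x$phi_bar),
      "   lower bound = ", format(x$g_lower_bound),
      "   gap = ", format(x$gap), "\n", sep = "")
  cat("  max sensitivity over X = ", format(x$max_sensitivity),
      "  (threshold ", format(x$threshold), ")\n", sep = "")
  cat("  support residuals: ",
      paste(format(x$support_residuals, digits = 3), collapse = ", "),
      "\n", sep = "")
  cat("  answering set size ", nrow(x$answering_set),
      "; mu search ", if (x$mu_converged) "converged" else
        "did not reach the loss target", "\n", sep = "")
  invisible(x)
}

#' Fixed-effects D-optimality sensitivity
#'
#' \eqn{f(x)^T M^{-1}(\xi) f(x) - p}: nonpositive everywhere exactly for
#' a D-optimal design, with roots at its support points.  Random effects
#' are ignored.
#'
#' @inheritParams sensitivity_g
#' @param x Evaluation point(s).
#' @export
sensitivity_d_fixed <- function(design, model, x) {
  parts <- crit_parts(design, model)
  X <- as_points_matrix(x, model$space$dim)
  Fg <- basis_matrix(model$basis, X)
  rowSums((Fg %*% parts$Minv) * Fg) - model$p
}

#' D-efficiency lower bound from the sensitivity maximum
#'
#' The Atwood-type bound \eqn{p / \bar d}, where \eqn{\bar d \ge p} is
#' the maximum of the D-optimality variance function of the candidate
#' design.  It bounds the design's D-efficiency from below without
#' knowing the optimum, and decreases as \eqn{\bar d} grows.
#'
#' @param p Number of model parameters.
#' @param d_bar Maximum of the sensitivity (variance-function form).
#' @export
d_efficiency_lower_bound <- function(p, d_bar) {
  if (d_bar < p) {
    stop("`d_bar` below p is impossible for a valid design ",
         "(got ", format(d_bar), " < ", p, ").")
  }
  p / d_bar
}
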