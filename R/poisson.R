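# Locally D-optimal design machinery for mixed-effects Poisson
# regression, built on the quasi-likelihood information matrix.
#
# With normal random coefficients b ~ (beta, D) and log link, the
# marginal intensity at x is mu(x) = exp(f'beta + f'Df/2) and responses
# taken at settings x, x' of the same individual are correlated through
# e(x, x') = exp(f(x)' D f(x')).  Writing F for the support basis
# matrix, w for the weights and C = exp(F D F') - J, the
# quasi-information of a design is
#   M(xi) = F' (diag(1/(w mu)) + C)^{-1} F,
# which reduces to the Poisson GLM information sum w lambda f f' when
# D = 0.

poisson_intensity_parts <- function(model, X, w = NULL) {
  Fm <- basis_matrix(model$basis, X)
  eta <- drop(Fm %*% model$beta)
  qf <- rowSums((Fm %*% model$D) * Fm)
  log_mu <- eta + qf / 2
  bad <- which(abs(log_mu) > 50)
  if (length(bad)) {
    stop("Linear predictor magnitude exceeds 50 at support point ",
         bad[1], "; intensities would overflow.")
  }
  list(F = Fm, mu = exp(log_mu))
}

#' Quasi-information matrix of a design for a Poisson mixed model
#'
#' The quasi-likelihood information accounting for the within-individual
#' correlation induced by the random coefficients (see the package
#' vignette for the derivation).  When `D = 0` it equals the standard
#' Poisson GLM information \eqn{\sum_l w_l \lambda(x_l) f(x_l)
#' f(x_l)^T} with \eqn{\lambda(x) = \exp(f(x)^T\beta)}.
#'
#' @param design A design tibble with strictly positive weights.
#' @param model A [poisson_model()].
#' @return A symmetric `p x p` matrix.
#' @export
quasi_information <- function(design, model) {
  check_design(design, model$space)
  if (any(design$weight <= 0)) {
    stop("quasi_information() needs strictly positive weights; ",
         "normalize_design() first.")
  }
  X <- design_points(design)
  ip <- poisson_intensity_parts(model, X)
  A <- diag(1 / (design$weight * ip$mu), nrow = nrow(X)) +
    exp(ip$F %*% model$D %*% t(ip$F)) - 1
  sym(crossprod(ip$F, solve(A, ip$F)))
}

#' Log-determinant D-criterion for the Poisson mixed model
#'
#' \eqn{\log|M(\xi)|} of the [quasi_information()]; the locally
#' D-optimal design maximizes it at the nominal `beta`.  A singular
#' quasi-information yields `-Inf` so optimizers reject the design.
#'
#' @inheritParams quasi_information
#' @export
d_criterion_poisson <- function(design, model) {
  M <- quasi_information(design, model)
  dt <- determinant(M, logarithm = TRUE)
  if (dt$sign <= 0) return(-Inf)
  v <- as.numeric(dt$modulus)
  if (!is.finite(v)) -Inf else v
}

#' Sensitivity function for Poisson mixed-model D-optimality
#'
#' The directional-derivative sensitivity in variance-function form.
#' With \eqn{g(x) = f(x) - F^T A^{-1} c(x)} (the basis vector at `x`
#' residualized on the correlated support, where \eqn{c(x)_l =
#' e(x_l, x) - 1}), the function is
#' \deqn{d(x, \xi) = \mu(x)\, g(x)^T M^{-1}(\xi) g(x) + p - T(\xi),
#'   \quad T(\xi) = \sum_l w_l \mu_l g_l^T M^{-1} g_l,}
#' calibrated so that a D-optimal design satisfies \eqn{d(x, \xi) \le p}
#' everywhere with equality at its support points.  For `D = 0` it
#' reduces to the familiar \eqn{\lambda(x) f^T M^{-1} f}.
#'
#' @inheritParams quasi_information
#' @param x Evaluation point(s).
#' @export
sensitivity_poisson <- function(design, model, x) {
  check_design(design, model$space)
  Xs <- design_points(design)
  ip <- poisson_intensity_parts(model, Xs)
  w <- design$weight
  A <- diag(1 / (w * ip$mu), nrow = nrow(Xs)) +
    exp(ip$F %*% model$D %*% t(ip$F)) - 1
  M <- sym(crossprod(ip$F, solve(A, ip$F)))
  Minv <- safe_inv(M, "quasi-information matrix")

  sens_raw <- function(X) {
    ipe <- poisson_intensity_parts(model, X)
    Ccross <- exp(ip$F %*% model$D %*% t(ipe$F)) - 1   # k x ne
    G <- ipe$F - t(Ccross) %*% solve(A, ip$F)          # ne x p
    ipe$mu * rowSums((G %*% Minv) * G)
  }
  Tterm <- sum(w * sens_raw(Xs))
  sens_raw(as_points_matrix(x, model$space$dim)) + model$p - Tterm
}

#' Search for a locally D-optimal design for a Poisson mixed model
#'
#' Single-layer competitive swarm search over support points and
#' weights, maximizing [d_criterion_poisson()].  Each restart's design
#' is scored by the Atwood-type efficiency bound
#' \eqn{p / \max_x d(x, \xi)} from [sensitivity_poisson()], and the
#' reported `efficiency_bound` is the minimum across restarts -- a
#' conservative statement of how good the search outcome is.
#'
#' @param model A [poisson_model()].
#' @param k Number of support-point slots (default `p + 1`; optima need
#'   not be minimally supported, so generous `k` is safer).
#' @param config [cso_config()] for the search.
#' @param restarts Independent swarm runs.
#' @param seed Integer seed.
#' @return A `design_fit` with `criterion = "D_poisson"`, `value` (the
#'   log-determinant), `efficiency_bound`, and per-restart diagnostics.
#' @export
find_locally_d_optimal_poisson <- function(model, k = NULL,
                                           config = cso_config(swarm = 128L,
                                                               max_iter = 350L),
                                           restarts = 5L, seed = 1L) {
  sp <- model$space
  k <- as.integer(k %||% (model$p + 1L))
  obj <- function(par) {
    cand <- particle_to_design(par, sp, k, NULL)
    keep <- cand$weights > 1e-9
    if (sum(keep) < model$p) return(Inf)
    des <- design(cand$points[keep, , drop = FALSE], cand$weights[keep])
    v <- tryCatch(-d_criterion_poisson(des, model), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }
  bnd <- particle_bounds(sp, k, NULL)
  set.seed(seed)
  runs <- lapply(seq_len(restarts), function(r) {
    cfg <- config
    cfg$seed <- NULL
    res <- cso_minimize(obj, bnd$lower, bnd$upper, cfg)
    cand <- particle_to_design(res$par, sp, k, NULL)
    des <- normalize_design(design(cand$points, cand$weights), space = sp)
    val <- d_criterion_poisson(des, model)
    dbar <- maximize_over_space(function(X) sensitivity_poisson(des, model, X),
                                sp, grid_n = 501)$value
    list(design = des, value = val,
         bound = model$p / max(dbar, model$p), history = res$history)
  })
  vals <- vapply(runs, `[[`, 0, "value")
  best <- runs[[which.max(vals)]]
  structure(
    list(design = best$design, value = best$value, criterion = "D_poisson",
         argmax = NULL, report = NULL, model = model,
         history = best$history,
         efficiency_bound = min(vapply(runs, `[[`, 0, "bound")),
         bounds_by_restart = vapply(runs, `[[`, 0, "bound"),
         restarts = restarts, seed = seed),
    class = "design_fit"
  )
}
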