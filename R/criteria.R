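# Design criteria for hierarchical linear models: information and MSE
# matrices, the prediction variance function phi, the G- and prediction
# D-criteria, efficiencies, and the BLUE/BLUP estimators.

sym <- function(M) (M + t(M)) / 2

safe_inv <- function(M, context = "matrix") {
  out <- tryCatch(chol2inv(chol(sym(M))), error = function(e) NULL)
  if (is.null(out)) {
    out <- tryCatch(solve(sym(M)), error = function(e) {
      stop("Numerically singular ", context,
           "; consider regularize() or a richer design.")
    })
  }
  out
}

# shared building blocks: F, M, M^{-1}, N(xi, Delta)
crit_parts <- function(design, model, reg = 0) {
  check_design(design)
  Fm <- basis_matrix(model$basis, design_points(design))
  M <- sym(crossprod(Fm, design$weight * Fm))
  if (reg > 0) M <- M + reg * diag(model$p)
  Minv <- safe_inv(M, "information matrix M(xi)")
  Delta <- model$Delta
  N <- sym(Delta - Delta %*% solve(Minv + Delta, Delta))
  list(F = Fm, M = M, Minv = Minv, Delta = Delta, N = N)
}

#' Standardized information matrix of a design
#'
#' \eqn{M(\xi) = \sum_l w_l f(x_l) f(x_l)^T}, the per-observation
#' information of the fixed-effects part of the model.
#'
#' @param design A design tibble (see [design()]).
#' @param model An [hlm_model()] (a [poisson_model()]'s basis works too,
#'   but see [quasi_information()] for its proper information matrix).
#' @return A symmetric `p x p` matrix.
#' @export
information_matrix <- function(design, model) {
  check_design(design)
  Fm <- basis_matrix(model$basis, design_points(design))
  sym(crossprod(Fm, design$weight * Fm))
}

#' Random-effects adjustment matrix N(xi, Delta)
#'
#' \eqn{N(\xi, \Delta) = \Delta - \Delta (M^{-1}(\xi) + \Delta)^{-1}
#' \Delta} with \eqn{\Delta = m D}.  This form stays valid for singular
#' `D`; for nonsingular `D` it equals \eqn{(M(\xi) + \Delta^{-1})^{-1}}.
#'
#' @inheritParams information_matrix
#' @return A symmetric positive semi-definite `p x p` matrix.
#' @export
n_matrix <- function(design, model) {
  crit_parts(design, model)$N
}

#' Mean squared error matrix of the individual predictions
#'
#' The `np x np` MSE matrix of the stacked individual predictors,
#' \deqn{(\sigma^2/m)\{ (1/n) J_n \otimes M^{-1}(\xi) +
#'   (I_n - (1/n) J_n) \otimes N(\xi, \Delta) \},}
#' built from the all-ones matrix \eqn{J_n} and the identity
#' \eqn{I_n}.  Its eigenvalues are those of \eqn{(\sigma^2/m) M^{-1}}
#' (each once) and of \eqn{(\sigma^2/m) N} (each `n - 1` times).
#'
#' @inheritParams information_matrix
#' @return An object of class `mse_matrix`: the full matrix plus the
#'   `Minv` and `N` blocks and `Delta`.
#' @export
mse_matrix <- function(design, model) {
  parts <- crit_parts(design, model)
  n <- model$n
  Jn <- matrix(1, n, n)
  In <- diag(n)
  s <- model$sigma2 / model$m
  full <- s * (kronecker(Jn / n, parts$Minv) +
                 kronecker(In - Jn / n, parts$N))
  structure(list(full = sym(full), Minv = parts$Minv, N = parts$N,
                 Delta = parts$Delta, sigma2 = model$sigma2, m = model$m,
                 n = n),
            class = "mse_matrix")
}

#' Prediction variance function phi(x, xi)
#'
#' \eqn{\phi(x, \xi) = f(x)^T M^{-1}(\xi) f(x) + (n - 1) f(x)^T
#' N(\xi, \Delta) f(x)}, the summed expected squared prediction error of
#' the individual responses at `x` (up to the factor \eqn{\sigma^2/m}).
#' For `D = 0` it reduces to the familiar fixed-effects variance
#' function \eqn{f^T M^{-1} f}.
#'
#' @inheritParams information_matrix
#' @param x Evaluation point(s): vector, matrix (rows are points), or a
#'   tibble with `x1..xd` columns.
#' @param parts Optional precomputed matrix blocks (internal use).
#' @return Numeric vector of \eqn{\phi} values.
#' @export
phi <- function(design, model, x, parts = NULL) {
  if (is.null(parts)) parts <- crit_parts(design, model)
  X <- as_points_matrix(x, model$space$dim)
  if (!space_contains(model$space, X, tol = 1e-7)) {
    stop("phi() evaluated outside the design space.")
  }
  Fg <- basis_matrix(model$basis, X)
  rowSums((Fg %*% parts$Minv) * Fg) +
    (model$n - 1) * rowSums((Fg %*% parts$N) * Fg)
}

# candidate local maxima of gridded values, with per-axis parabolic
# refinement of their locations (no extra function evaluations); the
# caller re-evaluates exactly at the refined points.  This matters:
# sharp peaks between grid nodes would otherwise be underestimated, and
# an outer minimizer of the grid maximum would exploit exactly that.
refine_grid_candidates <- function(v, ax) {
  d <- length(ax)
  refine1 <- function(x, vm, vc, vp, h) {
    den <- 2 * vc - vm - vp
    if (!is.finite(den) || den <= 0) return(x)
    x + pmin(pmax(h / 2 * (vp - vm) / den, -h), h)
  }
  if (d == 1) {
    n <- length(v)
    loc <- which(diff(sign(diff(v))) < 0) + 1L
    idx <- unique(c(1L, loc, n))
    h <- ax[[1]][2] - ax[[1]][1]
    xs <- vapply(idx, function(i) {
      if (i == 1L || i == n) ax[[1]][i]
      else refine1(ax[[1]][i], v[i - 1], v[i], v[i + 1], h)
    }, 0)
    matrix(xs, ncol = 1L)
  } else {
    n1 <- length(ax[[1]]); n2 <- length(ax[[2]])
    V <- matrix(v, n1, n2)
    P <- matrix(-Inf, n1 + 2, n2 + 2)
    P[2:(n1 + 1), 2:(n2 + 1)] <- V
    is_max <- V >= P[1:n1, 2:(n2 + 1)] & V >= P[3:(n1 + 2), 2:(n2 + 1)] &
      V >= P[2:(n1 + 1), 1:n2] & V >= P[2:(n1 + 1), 3:(n2 + 2)]
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) > 16) idx <- idx[order(-V[idx])[1:16], , drop = FALSE]
    h1 <- ax[[1]][2] - ax[[1]][1]; h2 <- ax[[2]][2] - ax[[2]][1]
    t(apply(idx, 1, function(ij) {
      i <- ij[1]; j <- ij[2]
      x <- ax[[1]][i]; y <- ax[[2]][j]
      if (i > 1 && i < n1) x <- refine1(x, V[i - 1, j], V[i, j], V[i + 1, j], h1)
      if (j > 1 && j < n2) y <- refine1(y, V[i, j - 1], V[i, j], V[i, j + 1], h2)
      c(x, y)
    }))
  }
}

# maximize a scalar function over the design space: deterministic dense
# grid, parabolic refinement of every local maximum with exact
# re-evaluation, and (optionally) a final local polish -- for dim <= 2;
# seeded CSO for dim >= 3
maximize_over_space <- function(fn, space, grid_n = 2001, polish = TRUE,
                                cso = NULL) {
  d <- space$dim
  if (d <= 2) {
    ax <- lapply(seq_len(d), function(j) {
      seq(space$lower[j], space$upper[j],
          length.out = if (d == 1) grid_n else min(grid_n, 201))
    })
    X <- as.matrix(expand.grid(ax))
    v <- fn(X)
    cand <- refine_grid_candidates(v, ax)
    cand <- sweep(sweep(cand, 2, space$lower, pmax), 2, space$upper, pmin)
    vc <- fn(cand)
    i <- which.max(vc)
    best <- list(par = cand[i, ], value = vc[i])
    gi <- which.max(v)
    if (v[gi] > best$value) best <- list(par = X[gi, ], value = v[gi])
    if (polish) {
      x0 <- best$par
      step <- (space$upper - space$lower) / (vapply(ax, length, 1L) - 1)
      lo <- pmax(space$lower, x0 - 2 * step)
      hi <- pmin(space$upper, x0 + 2 * step)
      op <- tryCatch(
        if (d == 1) {
          o <- stats::optimize(function(z) fn(matrix(z, 1, 1)),
                               lower = lo, upper = hi, maximum = TRUE,
                               tol = 1e-10)
          list(par = o$maximum, value = o$objective)
        } else {
          o <- stats::optim(x0, function(z) -fn(matrix(z, 1, d)),
                            method = "L-BFGS-B", lower = lo, upper = hi)
          list(par = o$par, value = -o$value)
        },
        error = function(e) NULL)
      if (!is.null(op) && op$value > best$value) best <- op
    }
    best
  } else {
    cfg <- cso %||% cso_config(swarm = 64, max_iter = 150)
    res <- cso_minimize(function(z) -fn(matrix(z, 1, d)),
                        space$lower, space$upper, cfg)
    # local polish from the CSO solution
    op <- tryCatch(
      stats::optim(res$par, function(z) -fn(matrix(z, 1, d)),
                   method = "L-BFGS-B",
                   lower = space$lower, upper = space$upper),
      error = function(e) NULL)
    if (!is.null(op) && -op$value > -res$value) {
      list(par = op$par, value = -op$value)
    } else {
      list(par = res$par, value = -res$value)
    }
  }
}

#' G-criterion for prediction
#'
#' \eqn{\psi_G(\xi) = \max_{x \in \mathcal{X}} \phi(x, \xi)}.  The inner
#' maximization uses a deterministic dense grid with local polish for
#' one- and two-factor spaces (2001 points per axis by default) and a
#' seeded competitive swarm search for three or more factors.
#'
#' @inheritParams information_matrix
#' @param grid_n Grid resolution per axis for the inner maximization.
#' @param reg Ridge added to `M` before inversion (0 = none; the
#'   optimizer uses `1e-7` during search, certification uses 0).
#' @return A `criterion_value` object: `value`, `criterion = "G_pred"`,
#'   and the inner maximizer `argmax`.
#' @export
g_criterion <- function(design, model, grid_n = 2001, reg = 0) {
  parts <- crit_parts(design, model, reg = reg)
  fn <- function(X) phi(design, model, X, parts = parts)
  best <- maximize_over_space(fn, model$space, grid_n = grid_n)
  structure(list(value = best$value, criterion = "G_pred",
                 argmax = best$par),
            class = "criterion_value")
}

#' @export
print.criterion_value <- function(x, ...) {
  cat("<criterion_value> ", x$criterion, " = ", format(x$value), sep = "")
  if (!is.null(x$argmax)) {
    cat("  (argmax ", paste(format(x$argmax, digits = 4), collapse = ", "),
        ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Lower bound on the G-criterion
#'
#' For every design, \eqn{\max_x \phi(x, \xi) \ge p + (n - 1)
#' \mathrm{tr}\{(M^{-1}(\xi) + \Delta)^{-1} \Delta\}}.  Equality at the
#' support points certifies G-optimality.  For a random-intercept model
#' the bound collapses to the design-free value
#' \eqn{p + (n-1)\delta/(1+\delta)} (see [random_intercept_g_bound()]).
#'
#' @inheritParams information_matrix
#' @return The bound (a scalar).
#' @export
g_lower_bound <- function(design, model) {
  parts <- crit_parts(design, model)
  model$p + (model$n - 1) *
    sum(diag(solve(parts$Minv + parts$Delta, parts$Delta)))
}

#' Prediction D-criterion
#'
#' The log-volume criterion for predicting the individual parameters,
#' \deqn{\psi_D(\xi) = \frac{1}{m}\Big[\ln\det M^{-1}(\xi) + (n-1)
#'   \ln \prod_{l=1}^{q} \lambda_l(\xi, \Delta)\Big],}
#' where \eqn{\lambda_1 \ge \dots \ge \lambda_q} are the `q = rank(D)`
#' largest eigenvalues of \eqn{N(\xi, \Delta)}.  Smaller is better.  The
#' `1/m` standardization matches the scale on which worked examples for
#' this criterion are usually reported; it is a monotone rescaling and
#' leaves the optimal design unchanged.  For `D = 0` the criterion
#' reduces to \eqn{-\ln\det M(\xi) / m}.
#'
#' @inheritParams information_matrix
#' @param reg Ridge added to `M` during optimization (default 0).
#' @return A `criterion_value` with `criterion = "D_pred"`.
#' @export
d_pred_criterion <- function(design, model, reg = 0) {
  parts <- crit_parts(design, model, reg = reg)
  q <- model$q
  val <- -determinant(parts$M, logarithm = TRUE)$modulus[1]
  if (q > 0) {
    lam <- sort(eigen(parts$N, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)[seq_len(q)]
    if (any(lam <= 0)) {
      stop("Degenerate design: the ", q,
           " leading eigenvalues of N(xi, Delta) are not all positive.")
    }
    val <- val + (model$n - 1) * sum(log(lam))
  }
  structure(list(value = as.numeric(val) / model$m, criterion = "D_pred",
                 argmax = NULL),
            class = "criterion_value")
}

#' Fixed-effects D-efficiency of a design relative to a reference
#'
#' \eqn{\{|M(\xi)| / |M(\xi_{ref})|\}^{1/p}}; equals 1 when the designs
#' share an information matrix, and 0.5 means the design must be run
#' twice to match the reference.
#'
#' @param design,reference Design tibbles.
#' @param model The model supplying the basis.
#' @export
d_efficiency_fixed <- function(design, reference, model) {
  ld <- function(d) determinant(information_matrix(d, model))$modulus[1]
  v <- exp((ld(design) - ld(reference)) / model$p)
  as.numeric(v)
}

#' Prediction-criterion efficiencies
#'
#' Package conventions for comparing designs under the prediction
#' criteria: G-efficiency is the criterion ratio
#' \eqn{\psi_G(\xi_{ref}) / \psi_G(\xi)} (the reference should be the
#' G-optimal design, making the ratio at most 1 up to tolerance), and
#' prediction D-efficiency is
#' \eqn{\exp\{ m[\psi_D(\xi_{ref}) - \psi_D(\xi)] / ((n-1)q + p) \}},
#' the volume ratio per effective dimension.
#'
#' @param design,reference Design tibbles.
#' @param model An [hlm_model()].
#' @param kind `"G"` or `"D"`.
#' @return A scalar efficiency.
#' @export
pred_efficiency <- function(design, reference, model, kind = c("G", "D")) {
  kind <- match.arg(kind)
  if (kind == "G") {
    g_criterion(reference, model)$value / g_criterion(design, model)$value
  } else {
    df <- d_pred_criterion(reference, model)$value -
      d_pred_criterion(design, model)$value
    exp(model$m * df / ((model$n - 1) * model$q + model$p))
  }
}

#' BLUE of the population parameter and BLUPs of individual parameters
#'
#' Given the common individual design matrix `F` (`m x p`) and the
#' response matrix `Y` (`n x m`, one row per individual), computes the
#' best linear unbiased estimator \eqn{\hat\beta = (F^TF)^{-1} F^T \bar Y}
#' and the predictors
#' \eqn{\hat\beta_i = D((F^TF)^{-1} + D)^{-1} \hat\beta_{i;ind} +
#' (F^TF)^{-1}((F^TF)^{-1} + D)^{-1} \hat\beta}, the shrinkage
#' combination of each individual least-squares estimate and the
#' population estimate.  With `D = 0` every \eqn{\hat\beta_i} collapses
#' to \eqn{\hat\beta}; as `D` grows they approach the individual
#' estimates.
#'
#' @param Y `n x m` numeric matrix of responses.
#' @param model An [hlm_model()] supplying `D` and the basis.
#' @param settings The `m` experimental settings (vector or matrix) at
#'   which every individual is observed.
#' @return A list with `beta_hat` (length `p`) and `beta_i`
#'   (`n x p` matrix of individual predictors).
#' @export
blup <- function(Y, model, settings) {
  Fm <- basis_matrix(model$basis, settings)
  if (qr(Fm)$rank < ncol(Fm)) {
    stop("Design matrix F is rank deficient; the BLUE is undefined.")
  }
  Y <- as.matrix(Y)
  if (ncol(Y) != nrow(Fm)) stop("`Y` must be n x m with m = nrow(F).")
  FtF_inv <- safe_inv(crossprod(Fm), "F'F")
  ybar <- colMeans(Y)
  beta_hat <- drop(FtF_inv %*% crossprod(Fm, ybar))
  beta_ind <- Y %*% Fm %*% FtF_inv          # n x p, rows are beta_i;ind
  W <- solve(FtF_inv + model$D)
  shrink_ind <- model$D %*% W               # weight on individual estimate
  shrink_pop <- FtF_inv %*% W               # weight on population estimate
  beta_i <- beta_ind %*% t(shrink_ind) +
    matrix(beta_hat, nrow(Y), model$p, byrow = TRUE) %*% t(shrink_pop)
  list(beta_hat = beta_hat, beta_i = beta_i)
}
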