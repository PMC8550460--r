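# Model and design-space representations.

#' Define a box design space
#'
#' An axis-aligned box \eqn{\mathcal{X} = [l_1, u_1] \times \dots \times
#' [l_d, u_d]} on which designs live.
#'
#' @param lower,upper Numeric vectors of per-factor bounds with
#'   `lower[j] < upper[j]`.
#' @return A `design_space` object with fields `lower`, `upper`, `dim`.
#' @export
#' @examples
#' design_space(0, 2)          # the interval [0, 2]
#' design_space(c(-1, -1), c(1, 1))  # the square [-1, 1]^2
design_space <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper)) stop("Bound vectors differ in length.")
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("Design-space bounds must be finite.")
  }
  if (any(lower >= upper)) stop("Each lower bound must be below its upper bound.")
  structure(list(lower = lower, upper = upper, dim = length(lower)),
            class = "design_space")
}

#' @export
print.design_space <- function(x, ...) {
  cat("<design_space> ",
      paste(sprintf("[%g, %g]", x$lower, x$upper), collapse = " x "), "\n")
  invisible(x)
}

space_contains <- function(space, X, tol = 1e-9) {
  X <- as_points_matrix(X, space$dim)
  rng <- space$upper - space$lower
  all(sweep(X, 2, space$lower) >= -tol * rng) &&
    all(sweep(X, 2, space$upper) <= tol * rng)
}

check_psd <- function(D, name = "D", tol = 1e-10) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("`", name, "` must be square.")
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D)))) {
    stop("`", name, "` must be symmetric.")
  }
  ev <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev)))) {
    stop("`", name, "` must be positive semi-definite (min eigenvalue ",
         format(min(ev)), ").")
  }
  invisible(TRUE)
}

#' Rank of a covariance matrix by eigenvalue thresholding
#'
#' The number of eigenvalues exceeding `tol` times the largest absolute
#' eigenvalue.  Used for the number \eqn{q} of random coefficients when
#' the dispersion matrix is singular.
#'
#' @param D Symmetric positive semi-definite matrix.
#' @param tol Relative eigenvalue threshold (default `1e-10`).
#' @export
rank_psd <- function(D, tol = 1e-10) {
  ev <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(abs(ev))
  if (mx == 0) return(0L)
  sum(ev > tol * mx)
}

#' Specify a hierarchical linear model
#'
#' The model \eqn{y_{ij} = f(x_j)^T \beta_i + \varepsilon_{ij}} for
#' individuals \eqn{i = 1, \dots, n}, each observed \eqn{m} times under a
#' common regime.  Individual coefficient vectors \eqn{\beta_i} have mean
#' \eqn{\beta} and covariance \eqn{\sigma^2 D}; errors are uncorrelated
#' with variance \eqn{\sigma^2}.  `D` may be singular (non-random
#' coefficients get zero rows and columns).
#'
#' @param basis A [regression_basis()] with `p` terms.
#' @param D `p x p` symmetric positive semi-definite dispersion matrix,
#'   in units of \eqn{\sigma^2}.
#' @param n Number of individuals (`>= 1`).
#' @param m Observations per individual (`>= 1`).
#' @param space The [design_space()].
#' @param sigma2 Error variance (default 1; a monotone scaling of all
#'   criteria, so it does not affect optimal designs).
#' @return An object of class `hlm_model`.
#' @export
#' @examples
#' mod <- hlm_model(poly_basis(2), D = diag(c(0.2, 0.2, 0.3)),
#'                  n = 10, m = 5, space = design_space(0, 2))
hlm_model <- function(basis, D, n, m, space, sigma2 = 1) {
  stopifnot(inherits(basis, "regression_basis"), inherits(space, "design_space"))
  D <- as.matrix(D)
  if (nrow(D) != basis$p) stop("`D` must be ", basis$p, " x ", basis$p, ".")
  check_psd(D)
  if (space$dim != basis$dim) stop("Design space and basis dimension differ.")
  if (n < 1 || m < 1) stop("`n` and `m` must be at least 1.")
  if (sigma2 <= 0) stop("`sigma2` must be positive.")
  structure(
    list(basis = basis, D = D, n = as.integer(n), m = as.integer(m),
         sigma2 = sigma2, space = space, p = basis$p,
         Delta = m * D, q = rank_psd(D)),
    class = "hlm_model"
  )
}

#' @export
print.hlm_model <- function(x, ...) {
  cat("<hlm_model> p =", x$p, " n =", x$n, " m =", x$m,
      " rank(D) =", x$q, "\n")
  cat("  f(x) = (", paste(x$basis$labels, collapse = ", "), ")\n")
  print(x$space)
  invisible(x)
}

#' Specify a mixed-effects Poisson regression model
#'
#' Counts \eqn{Y_{ij} \sim Poisson(\lambda_{ij})} with log-linear
#' conditional intensity \eqn{\lambda_{ij} = \exp(f(x_{ij})^T b_i)},
#' where the individual coefficients \eqn{b_i} have mean `beta` and
#' covariance `D` (zero rows/columns mark fixed coefficients).  Designs
#' for this model are locally D-optimal at the nominal `beta`.
#'
#' @param basis A [regression_basis()] (main effects plus interaction
#'   products).
#' @param beta Nominal coefficient vector, length `p`.
#' @param D `p x p` symmetric PSD covariance of the random coefficients.
#' @param space The [design_space()].
#' @return An object of class `poisson_model`.
#' @export
poisson_model <- function(basis, beta, D, space) {
  stopifnot(inherits(basis, "regression_basis"), inherits(space, "design_space"))
  beta <- as.numeric(beta)
  if (length(beta) != basis$p) stop("`beta` must have length ", basis$p, ".")
  D <- as.matrix(D)
  if (nrow(D) != basis$p) stop("`D` must be ", basis$p, " x ", basis$p, ".")
  check_psd(D)
  # zero-variance coefficients must have zero covariances too
  zv <- diag(D) == 0
  if (any(zv) && (any(D[zv, , drop = FALSE] != 0) ||
                    any(D[, zv, drop = FALSE] != 0))) {
    stop("Coefficients with zero variance must have zero covariances.")
  }
  if (space$dim != basis$dim) stop("Design space and basis dimension differ.")
  structure(
    list(basis = basis, beta = beta, D = D, space = space, p = basis$p,
         q = rank_psd(D)),
    class = "poisson_model"
  )
}

#' @export
print.poisson_model <- function(x, ...) {
  cat("<poisson_model> p =", x$p, " rank(D) =", x$q, "\n")
  cat("  log-intensity: f(x)'b,  f = (",
      paste(x$basis$labels, collapse = ", "), ")\n")
  print(x$space)
  invisible(x)
}

#' Generate a random hierarchical linear model (test fixture)
#'
#' Draws a reproducible random model: a polynomial basis of random
#' degree, a random PSD dispersion matrix \eqn{D = A A^T} (optionally
#' with zeroed rows/columns to exercise singular cases), and random
#' counts.  Intended for property-style tests.
#'
#' @param seed Integer seed; the same seed yields the identical model.
#' @param max_degree Maximum polynomial degree (default 3).
#' @param n_range,m_range Integer ranges for the counts.
#' @param singular Force `rank(D) < p` by zeroing one row/column.
#' @param d_scale Scale of the entries of `D`.
#' @param space Design space (default the unit interval `[0.5, 2]`,
#'   bounded away from 0 so fractional terms stay finite).
#' @return An `hlm_model`.
#' @export
random_hlm <- function(seed, max_degree = 3, n_range = c(2L, 15L),
                       m_range = c(2L, 8L), singular = FALSE, d_scale = 0.5,
                       space = design_space(0.5, 2)) {
  set.seed(seed)
  deg <- sample(seq_len(max_degree), 1L)
  basis <- poly_basis(deg)
  p <- basis$p
  A <- matrix(stats::rnorm(p * p, sd = sqrt(d_scale)), p, p)
  D <- A %*% t(A)
  if (singular) {
    j <- sample(p, 1L)
    D[j, ] <- 0
    D[, j] <- 0
  }
  n <- sample(seq(n_range[1], n_range[2]), 1L)
  m <- sample(seq(m_range[1], m_range[2]), 1L)
  hlm_model(basis, D, n = n, m = m, space = space)
}
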