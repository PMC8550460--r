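# Regression bases: polynomials, fractional polynomials (Box-Tidwell
# convention), and multi-factor bases with interaction products.

#' Practical fractional-polynomial power set
#'
#' The conventional set of powers used for fractional polynomials,
#' \eqn{\mathcal{P} = \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}}, where power 0
#' stands for \eqn{\ln x} under the Box-Tidwell transformation.
#'
#' @export
fp_power_set <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Create a single basis term
#'
#' Terms come in three kinds.  `"constant"` is the intercept.  `"power"`
#' is a single-factor Box-Tidwell term \eqn{x^{(p)}}: \eqn{x^p} for
#' \eqn{p \neq 0} and \eqn{\ln x} for \eqn{p = 0}; a positive
#' `ln_mult` multiplies the term by \eqn{\ln[x]^{ln\_mult}}, which is how
#' repeated powers enter a fractional polynomial.  `"product"` is a plain
#' monomial in several factors (an interaction such as \eqn{x_1 x_2});
#' exponent 0 means the factor is absent.
#'
#' @param kind One of `"constant"`, `"power"`, `"product"`.
#' @param factor Factor index for `"power"` terms.
#' @param power Real exponent for `"power"` terms (0 means `ln`).
#' @param exponents Named or positional exponent vector for `"product"`
#'   terms; at least two factors must have a nonzero exponent.
#' @param ln_mult Nonnegative integer multiplicity of the `ln[x]` factor
#'   attached to a `"power"` term.
#' @return A `basis_term` object.
#' @export
basis_term <- function(kind = c("constant", "power", "product"),
                       factor = 1L, power = 1, exponents = NULL,
                       ln_mult = 0L) {
  kind <- match.arg(kind)
  ln_mult <- as.integer(ln_mult)
  if (ln_mult < 0) stop("`ln_mult` must be a nonnegative integer.")
  if (kind != "power" && ln_mult > 0) {
    stop("`ln_mult` > 0 is only meaningful for a \"power\" base term.")
  }
  if (kind == "product") {
    if (is.null(exponents) || sum(exponents != 0) < 2) {
      stop("A \"product\" term must involve at least two factors.")
    }
  }
  structure(
    list(kind = kind, factor = as.integer(factor), power = power,
         exponents = exponents, ln_mult = ln_mult),
    class = "basis_term"
  )
}

term_label <- function(term) {
  base <- switch(term$kind,
    constant = "1",
    power = {
      v <- paste0("x", term$factor)
      if (term$power == 0) paste0("log(", v, ")")
      else if (term$power == 1) v
      else paste0(v, "^", format(term$power))
    },
    product = {
      j <- which(term$exponents != 0)
      paste(
        ifelse(term$exponents[j] == 1,
               paste0("x", j),
               paste0("x", j, "^", format(term$exponents[j]))),
        collapse = "*"
      )
    })
  if (term$ln_mult > 0) {
    v <- paste0("x", term$factor)
    base <- paste0(base, "*log(", v, ")",
                   if (term$ln_mult > 1) paste0("^", term$ln_mult) else "")
  }
  base
}

# does this term require strictly positive coordinates?
term_needs_positive <- function(term) {
  if (term$kind == "power") {
    term$power == 0 || term$power != round(term$power) ||
      term$power < 0 || term$ln_mult > 0
  } else {
    FALSE
  }
}

#' Assemble a regression basis from a list of terms
#'
#' @param terms List of [basis_term()] objects, in the order matching the
#'   coefficient vector of the model.
#' @param dim Number of factors (design-space dimension).
#' @return A `regression_basis` with `p = length(terms)` components.
#' @seealso [poly_basis()], [fp_basis()], [factor_basis()]
#' @export
regression_basis <- function(terms, dim = 1L) {
  stopifnot(length(terms) >= 1)
  if (!all(vapply(terms, inherits, logical(1), "basis_term"))) {
    stop("`terms` must be a list of `basis_term` objects.")
  }
  dim <- as.integer(dim)
  for (tm in terms) {
    if (tm$kind == "power" && tm$factor > dim) {
      stop("Term refers to factor ", tm$factor, " but dim = ", dim, ".")
    }
    if (tm$kind == "product" && length(tm$exponents) != dim) {
      stop("Product-term exponent vector must have length `dim`.")
    }
  }
  structure(
    list(terms = terms, p = length(terms), dim = dim,
         labels = vapply(terms, term_label, character(1))),
    class = "regression_basis"
  )
}

#' @export
print.regression_basis <- function(x, ...) {
  cat("<regression_basis> p =", x$p, "on", x$dim, "factor(s)\n")
  cat("  f(x) = (", paste(x$labels, collapse = ", "), ")\n")
  invisible(x)
}

#' Polynomial basis in one factor
#'
#' @param degree Polynomial degree; the basis is \eqn{(1, x, \dots, x^d)}.
#' @export
poly_basis <- function(degree) {
  stopifnot(degree >= 1)
  terms <- c(list(basis_term("constant")),
             lapply(seq_len(degree), function(d) basis_term("power", power = d)))
  regression_basis(terms, dim = 1L)
}

#' Fractional-polynomial basis in one factor
#'
#' Builds the basis \eqn{(1, H_1(x), \dots, H_t(x))} from a vector of
#' Box-Tidwell powers: \eqn{H_1(x) = x^{(p_1)}} and, sequentially,
#' \eqn{H_j(x) = x^{(p_j)}} when \eqn{p_j \neq p_{j-1}} or
#' \eqn{H_{j-1}(x)\,\ln[x]} when the power repeats.  Power 0 denotes
#' \eqn{\ln[x]}.  Evaluation requires \eqn{x > 0}.
#'
#' @param powers Numeric vector of powers \eqn{p_1 \le \dots \le p_t}.
#' @param intercept Include the constant term (default `TRUE`).
#' @param strict Restrict the powers to the conventional set
#'   [fp_power_set]; set to `FALSE` to allow arbitrary real powers.
#' @export
#' @examples
#' fp_basis(c(0.5, 1, 2))       # (1, sqrt(x), x, x^2)
fp_basis <- function(powers, intercept = TRUE, strict = TRUE) {
  stopifnot(length(powers) >= 1)
  if (is.unsorted(powers)) {
    stop("Fractional-polynomial powers must be nondecreasing.")
  }
  if (strict && !all(powers %in% fp_power_set)) {
    stop("Powers outside the conventional set ",
         "{-2, -1, -0.5, 0, 0.5, 1, 2, 3}; use `strict = FALSE` to allow.")
  }
  terms <- list()
  mult <- 0L
  for (j in seq_along(powers)) {
    if (j > 1 && powers[j] == powers[j - 1]) mult <- mult + 1L else mult <- 0L
    terms[[j]] <- basis_term("power", power = powers[j], ln_mult = mult)
  }
  if (intercept) terms <- c(list(basis_term("constant")), terms)
  regression_basis(terms, dim = 1L)
}

#' Multi-factor basis with main effects and interaction products
#'
#' @param dim Number of factors.
#' @param intercept Include a constant term.
#' @param interactions List of integer vectors, each naming the factors
#'   of one product term (e.g. `list(c(1, 2), c(1, 4))`).
#' @export
factor_basis <- function(dim, intercept = TRUE, interactions = list()) {
  dim <- as.integer(dim)
  terms <- lapply(seq_len(dim), function(j) basis_term("power", factor = j))
  if (intercept) terms <- c(list(basis_term("constant")), terms)
  for (ia in interactions) {
    e <- numeric(dim)
    e[ia] <- 1
    terms <- c(terms, list(basis_term("product", exponents = e)))
  }
  regression_basis(terms, dim = dim)
}

as_points_matrix <- function(x, dim) {
  if (is.data.frame(x)) x <- as.matrix(x[, grep("^x[0-9]+$", names(x)), drop = FALSE])
  if (is.null(nrow(x))) {
    x <- if (dim == 1L) matrix(x, ncol = 1L) else matrix(x, nrow = 1L)
  }
  if (ncol(x) != dim) {
    stop("Points have ", ncol(x), " coordinate(s); the basis expects ", dim, ".")
  }
  storage.mode(x) <- "double"
  x
}

eval_term <- function(term, X) {
  switch(term$kind,
    constant = rep(1, nrow(X)),
    power = {
      x <- X[, term$factor]
      if (term_needs_positive(term) && any(x <= 0)) {
        stop("Term `", term_label(term),
             "` requires strictly positive x", term$factor, ".")
      }
      v <- if (term$power == 0) log(x) else x^term$power
      if (term$ln_mult > 0) v <- v * log(x)^term$ln_mult
      v
    },
    product = {
      j <- which(term$exponents != 0)
      v <- rep(1, nrow(X))
      for (jj in j) v <- v * X[, jj]^term$exponents[jj]
      v
    })
}

#' Evaluate a regression basis
#'
#' `basis_eval()` evaluates \eqn{f(x)} at a single point; `basis_matrix()`
#' stacks \eqn{f(x)^T} row-wise over many points.
#'
#' @param basis A [regression_basis()].
#' @param x A point (numeric vector of length `dim`).
#' @param X Points: a numeric matrix with `dim` columns, a design tibble
#'   (its `x1..xd` columns are used), or a vector for one-factor bases.
#' @return `basis_eval()`: numeric vector of length `p`; `basis_matrix()`:
#'   numeric matrix, one row per point.
#' @export
#' @examples
#' basis_eval(fp_basis(c(0.5, 1, 2)), 4)   # c(1, 2, 4, 16)
basis_eval <- function(basis, x) {
  drop(basis_matrix(basis, matrix(x, nrow = 1L)))
}

#' @rdname basis_eval
#' @export
basis_matrix <- function(basis, X) {
  X <- as_points_matrix(X, basis$dim)
  out <- vapply(basis$terms, function(tm) eval_term(tm, X),
                numeric(nrow(X)))
  if (nrow(X) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- basis$labels
  out
}
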