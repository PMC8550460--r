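# Approximate designs as tibbles: one row per support point, coordinate
# columns x1..xd and a weight column.

#' Construct an approximate design
#'
#' An approximate design is a probability measure on the design space:
#' support points with nonnegative weights summing to one.  It is stored
#' as a tibble with columns `x1, .., xd` and `weight`, so it pipes
#' directly into the criterion and certification functions.
#'
#' @param points Support points: a numeric vector (one factor), or a
#'   matrix/data frame with one row per point.
#' @param weights Nonnegative weights; normalized to sum to one.
#' @return A design tibble.
#' @export
#' @examples
#' design(c(0, 1, 2), c(1, 1, 1))
#' design(rbind(c(0, 0), c(1, 1)), c(0.4, 0.6))
design <- function(points, weights = NULL) {
  if (is.data.frame(points)) {
    X <- as.matrix(points[, grep("^x[0-9]+$", names(points)), drop = FALSE])
    if (is.null(weights) && "weight" %in% names(points)) {
      weights <- points$weight
    }
  } else if (is.matrix(points)) {
    X <- points
  } else {
    X <- matrix(as.numeric(points), ncol = 1L)
  }
  k <- nrow(X)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k) stop("One weight per support point is required.")
  if (any(weights < 0)) stop("Weights must be nonnegative.")
  s <- sum(weights)
  if (s <= 0) stop("Total weight must be positive.")
  out <- tibble::as_tibble(as.data.frame(X, optional = TRUE),
                           .name_repair = "minimal")
  names(out) <- paste0("x", seq_len(ncol(X)))
  out$weight <- as.numeric(weights) / s
  out
}

#' Extract the support-point coordinates of a design as a matrix
#'
#' @param design A design tibble.
#' @return Numeric matrix, one row per support point.
#' @export
design_points <- function(design) {
  as.matrix(design[, grep("^x[0-9]+$", names(design)), drop = FALSE])
}

design_dim <- function(design) {
  length(grep("^x[0-9]+$", names(design)))
}

check_design <- function(design, space = NULL, tol = 1e-12) {
  w <- design$weight
  if (is.null(w)) stop("A design needs a `weight` column.")
  if (any(w < 0)) stop("Design weights must be nonnegative.")
  if (abs(sum(w) - 1) > 1e-8) stop("Design weights must sum to 1.")
  if (!is.null(space) && !space_contains(space, design_points(design))) {
    stop("Design has support points outside the design space.")
  }
  invisible(design)
}

#' Clean up an approximate design
#'
#' Merges support points closer than `merge_tol` (measured per axis in
#' units of the factor range when a `space` is supplied), dropping the
#' merged points at their weight-averaged location, prunes weights below
#' `prune_tol`, and renormalizes the weights to one.  Idempotent on
#' already-clean designs.
#'
#' @param design A design tibble.
#' @param space Optional [design_space()] used to scale `merge_tol`.
#' @param merge_tol Merge radius, default `1e-4` (times the factor range
#'   when `space` is given).
#' @param prune_tol Weights below this are dropped, default `1e-4`.
#' @return A design tibble.
#' @export
normalize_design <- function(design, space = NULL, merge_tol = 1e-4,
                             prune_tol = 1e-4) {
  X <- design_points(design)
  w <- design$weight
  if (any(w < 0)) stop("Design weights must be nonnegative.")
  if (sum(w) <= 0) stop("Total weight must be positive.")
  scale <- if (is.null(space)) rep(1, ncol(X)) else space$upper - space$lower
  Xs <- sweep(X, 2, scale, "/")

  # greedy union of points within merge_tol (max-coordinate metric)
  k <- nrow(X)
  grp <- seq_len(k)
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (max(abs(Xs[i, ] - Xs[j, ])) <= merge_tol) {
        grp[grp == grp[j]] <- grp[i]
      }
    }
  }
  ug <- unique(grp)
  Xm <- matrix(0, length(ug), ncol(X))
  wm <- numeric(length(ug))
  for (g in seq_along(ug)) {
    idx <- which(grp == ug[g])
    wm[g] <- sum(w[idx])
    Xm[g, ] <- if (wm[g] > 0) {
      colSums(X[idx, , drop = FALSE] * w[idx]) / wm[g]
    } else {
      colMeans(X[idx, , drop = FALSE])
    }
  }
  keep <- wm / sum(wm) >= prune_tol
  if (!any(keep)) stop("All support points were pruned; nothing remains.")
  out <- design(Xm[keep, , drop = FALSE], wm[keep])
  if (!is.null(space)) {
    # weight-averaging cannot leave the box, but guard against fp noise
    pts <- pmin(pmax(design_points(out),
                     matrix(space$lower, nrow(out), space$dim, byrow = TRUE)),
                matrix(space$upper, nrow(out), space$dim, byrow = TRUE))
    out <- design(pts, out$weight)
  }
  out
}

#' Round an approximate design to an exact N-observation design
#'
#' Converts weights to integer replicate counts summing exactly to `N`
#' by largest-remainder apportionment (floor each `N w_j`, then give the
#' leftover observations to the largest fractional remainders; ties go
#' to the larger weight, then to the earlier support point).
#'
#' @param design A design tibble.
#' @param N Total number of observations; at least the support size.
#' @return The design tibble with a `count` column replacing `weight`.
#' @export
round_to_exact <- function(design, N) {
  check_design(design)
  k <- nrow(design)
  N <- as.integer(N)
  if (N < k) stop("`N` (", N, ") is below the support size (", k, ").")
  tgt <- N * design$weight
  cnt <- floor(tgt)
  rem <- tgt - cnt
  left <- N - sum(cnt)
  if (left > 0) {
    ord <- order(-rem, -design$weight, seq_len(k))
    cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1
  }
  out <- design[, grep("^x[0-9]+$", names(design)), drop = FALSE]
  out$count <- as.integer(cnt)
  out
}

#' Read and write designs as TSV
#'
#' One row per support point, columns `x1..xd` then `weight`, printed
#' with six decimals.  `read_design()` re-normalizes the weights so the
#' round trip always yields a valid design.
#'
#' @param design A design tibble.
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   returns a design tibble.
#' @export
write_design <- function(design, path) {
  check_design(design)
  df <- as.data.frame(design)
  df[] <- lapply(df, function(col) sprintf("%.6f", col))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  design(df)
}

#' Draw a random design on a model's design space (test fixture)
#'
#' @param model An `hlm_model` or `poisson_model`.
#' @param k Number of support points.
#' @param seed Integer seed.
#' @return A design tibble with Dirichlet-uniform weights.
#' @export
random_design <- function(model, k = model$p + 1L, seed = 1L) {
  set.seed(seed)
  sp <- model$space
  X <- matrix(stats::runif(k * sp$dim, rep(sp$lower, each = k),
                           rep(sp$upper, each = k)), k, sp$dim)
  w <- stats::rexp(k)
  design(X, w)
}
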