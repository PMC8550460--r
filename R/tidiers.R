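# broom-style tidiers and ggplot2 autoplots for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted optimal design
#'
#' One row per support point with its coordinates and weight.
#'
#' @param x A `design_fit` from [find_g_optimal()],
#'   [find_d_optimal_pred()] or [find_locally_d_optimal_poisson()].
#' @param ... Unused.
#' @export
tidy.design_fit <- function(x, ...) {
  out <- x$design
  out$point <- seq_len(nrow(out))
  dplyr::relocate(out, "point")
}

#' @rdname tidy.design_fit
#' @export
glance.design_fit <- function(x, ...) {
  tibble::tibble(
    criterion = x$criterion,
    value = x$value,
    k = nrow(x$design),
    certified = if (is.null(x$report)) NA else x$report$pass,
    max_sensitivity = if (is.null(x$report)) {
      if (is.null(x$efficiency_bound)) NA_real_ else NA_real_
    } else {
      x$report$max_sensitivity
    },
    efficiency_bound = x$efficiency_bound %||% NA_real_,
    restarts = x$restarts,
    seed = x$seed
  )
}

#' Tidy a criterion evaluation
#'
#' One row: the criterion tag, its value, and (for the G-criterion) the
#' coordinates of the inner maximizer -- ready for `write.csv()`.
#'
#' @param x A `criterion_value` from [g_criterion()] or
#'   [d_pred_criterion()].
#' @param ... Unused.
#' @export
tidy.criterion_value <- function(x, ...) {
  out <- tibble::tibble(criterion = x$criterion, value = x$value)
  if (!is.null(x$argmax)) {
    am <- matrix(x$argmax, nrow = 1)
    colnames(am) <- paste0("argmax_x", seq_len(ncol(am)))
    out <- dplyr::bind_cols(out, tibble::as_tibble(am))
  }
  out
}

#' Tidy an optimality certificate
#'
#' One row per answering-set point with its measure weight and the
#' prediction variance there; `glance()` gives the one-row verdict.
#'
#' @param x An `optimality_report` from [verify_g_optimality()].
#' @param ... Unused.
#' @export
tidy.optimality_report <- function(x, ...) {
  out <- x$answering_set
  out$mu_weight <- x$mu$weight[match_rows(design_points(x$mu),
                                          as_points_matrix(out, ncol(design_points(x$mu))))]
  out
}

match_rows <- function(X, Y, tol = 1e-6) {
  vapply(seq_len(nrow(Y)), function(i) {
    d <- apply(abs(sweep(X, 2, Y[i, ])), 1, max)
    j <- which.min(d)
    if (d[j] <= tol * max(1, max(abs(Y[i, ])))) j else NA_integer_
  }, integer(1))
}

#' @rdname tidy.optimality_report
#' @export
glance.optimality_report <- function(x, ...) {
  tibble::tibble(
    pass = x$pass,
    phi_bar = x$phi_bar,
    lower_bound = x$g_lower_bound,
    gap = x$gap,
    max_sensitivity = x$max_sensitivity,
    max_abs_residual = max(abs(x$support_residuals)),
    threshold = x$threshold,
    answering_points = nrow(x$answering_set),
    mu_converged = x$mu_converged
  )
}

#' Sensitivity grid of a certified design
#'
#' Evaluates the prediction variance and the equivalence-theorem
#' sensitivity on a regular grid, ready for plotting or CSV export.
#'
#' @param report An `optimality_report`.
#' @param model The [hlm_model()] the report was computed for.
#' @param n Grid points per axis.
#' @return A tibble with columns `x1..xd`, `phi`, `sensitivity`.
#' @export
sensitivity_grid <- function(report, model, n = 501) {
  sp <- model$space
  ax <- lapply(seq_len(sp$dim), function(j) {
    seq(sp$lower[j], sp$upper[j],
        length.out = if (sp$dim == 1) n else min(n, 101))
  })
  X <- as.matrix(expand.grid(ax))
  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- paste0("x", seq_len(ncol(X)))
  out$phi <- phi(report$design, model, X)
  out$sensitivity <- sensitivity_g(report$design, model, report$mu, X)
  out
}

#' Plot the sensitivity function of a certified design
#'
#' For one-factor models, the sensitivity curve with the zero reference
#' line and the design's support points; for two factors, a filled
#' raster.  The design is G-optimal when the curve stays at or below
#' zero and touches it at the support points.
#'
#' @param object An `optimality_report`.
#' @param model The [hlm_model()] it belongs to.
#' @param n Grid resolution.
#' @param ... Unused.
#' @export
autoplot.optimality_report <- function(object, model, n = 501, ...) {
  grid <- sensitivity_grid(object, model, n = n)
  sup <- object$design
  if (design_dim(sup) == 1) {
    ggplot2::ggplot(grid, ggplot2::aes(.data$x1, .data$sensitivity)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
      ggplot2::geom_line(colour = "#2c7fb8") +
      ggplot2::geom_point(
        data = tibble::tibble(
          x1 = sup$x1,
          sensitivity = sensitivity_g(object$design, model, object$mu,
                                      design_points(sup))),
        colour = "#d95f02", size = 2) +
      ggplot2::labs(x = "x", y = "sensitivity",
                    title = "Equivalence-theorem sensitivity function") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(grid, ggplot2::aes(.data$x1, .data$x2,
                                       fill = .data$sensitivity)) +
      ggplot2::geom_raster() +
      ggplot2::geom_point(data = sup, ggplot2::aes(.data$x1, .data$x2),
                          inherit.aes = FALSE, colour = "white") +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(title = "Equivalence-theorem sensitivity function") +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.optimality_report
#' @export
autoplot.design_fit <- function(object, n = 501, ...) {
  if (is.null(object$report)) {
    stop("This fit carries no certificate; plot criteria directly or ",
         "run verify_g_optimality().")
  }
  autoplot.optimality_report(object$report, object$model, n = n, ...)
}
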