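# Closed-form results for the simple linear model with a random slope
# on [0, 1] and for random-intercept models; these double as analytic
# oracles for the swarm optimizer.

#' Random-slope model specification
#'
#' The model \eqn{y_{ij} = \beta_1 + \beta_{i2} x_j + \varepsilon_{ij}}
#' on \eqn{[0, 1]} with a fixed intercept and random slope of variance
#' \eqn{d \sigma^2}.  All closed forms below are driven by
#' \eqn{\delta = m d}.
#'
#' @param n Number of individuals.
#' @param m Observations per individual.
#' @param d Slope variance factor (`>= 0`).
#' @return A `random_slope_spec` with fields `n`, `m`, `d`, `delta`.
#' @export
random_slope_spec <- function(n, m, d) {
  stopifnot(n >= 1, m >= 1, d >= 0)
  structure(list(n = as.integer(n), m = as.integer(m), d = d,
                 delta = m * d),
            class = "random_slope_spec")
}

#' As an [hlm_model()]
#'
#' The random-slope specification as a full model object, for feeding
#' the generic criterion and optimizer machinery.
#'
#' @param spec A [random_slope_spec()].
#' @export
random_slope_model <- function(spec) {
  hlm_model(factor_basis(1, intercept = TRUE), D = diag(c(0, spec$d)),
            n = spec$n, m = spec$m, space = design_space(0, 1))
}

#' Optimal weight of the G-optimal two-point design
#'
#' The G-optimal design is supported on \eqn{\{0, 1\}} with weight at 1
#' \deqn{w^* = \frac{\sqrt{\delta^2 n^2 + 4\delta + 4} + n\delta - 2}
#' {2\delta(n + 1)}.}
#' The \eqn{\delta \to 0} limit is the balanced design (\eqn{w^* = 1/2});
#' as \eqn{\delta \to \infty}, \eqn{w^* \to n/(n+1)}.
#'
#' @param spec A [random_slope_spec()].
#' @export
random_slope_weight <- function(spec) {
  n <- spec$n; delta <- spec$delta
  if (delta == 0) return(0.5)
  (sqrt(delta^2 * n^2 + 4 * delta + 4) + n * delta - 2) /
    (2 * delta * (n + 1))
}

#' Prediction variance of the two-point random-slope design
#'
#' \eqn{\phi(x, \xi_w) = \big(\frac{1}{w - w^2} +
#' \frac{\delta(n-1)}{\delta w + 1}\big) x^2 + \frac{2}{w - 1} x -
#' \frac{1}{w - 1}}, a quadratic whose maximum over \eqn{[0,1]} sits at
#' the endpoints.
#'
#' @param spec A [random_slope_spec()].
#' @param w Weight at \eqn{x = 1} (strictly between 0 and 1).
#' @param x Evaluation points in \eqn{[0, 1]}.
#' @export
random_slope_phi <- function(spec, w, x) {
  stopifnot(w > 0, w < 1)
  n <- spec$n; delta <- spec$delta
  (1 / (w - w^2) + delta * (n - 1) / (delta * w + 1)) * x^2 +
    2 / (w - 1) * x - 1 / (w - 1)
}

#' Weight at 1 of the equivalence-theorem measure
#'
#' The measure \eqn{\mu^*} on \eqn{\{0, 1\}} certifying the optimality
#' of \eqn{\xi_{w^*}} puts mass
#' \deqn{w_\mu = \frac{\delta^2 w^{*4} + 2\delta w^{*3} + w^{*2}}
#' {(n+1)\delta^2 w^{*4} + (4\delta - 2n\delta^2) w^{*3} +
#'  (2 - 4\delta + n\delta^2) w^{*2} + 2(\delta - 1) w^* + 1}}
#' at \eqn{x = 1}.  The \eqn{\delta \to 0} limit is 1/2 by symmetry.
#'
#' @param spec A [random_slope_spec()].
#' @param w_star Optimal weight from [random_slope_weight()].
#' @export
random_slope_mu_weight <- function(spec, w_star = random_slope_weight(spec)) {
  n <- spec$n; delta <- spec$delta
  if (delta == 0) return(0.5)
  w <- w_star
  (delta^2 * w^4 + 2 * delta * w^3 + w^2) /
    ((n + 1) * delta^2 * w^4 + (4 * delta - 2 * n * delta^2) * w^3 +
       (2 - 4 * delta + n * delta^2) * w^2 + 2 * (delta - 1) * w + 1)
}

#' Closed-form sensitivity function of the random-slope design
#'
#' \deqn{\phi_G(x, \xi_{w^*}) = \Big(\frac{w^{*2} - 2 w^* w_\mu + w_\mu}
#' {w^{*2}(w^*-1)^2} + \frac{\delta^2 w_\mu (n-1)}{(\delta w^* + 1)^2}
#' \Big) x^2 + \frac{2(w_\mu - 1)}{(w^*-1)^2} x +
#' \frac{1 - w_\mu}{(w^*-1)^2},}
#' with maximum \eqn{(1 - w_\mu)/(w^* - 1)^2} attained at both
#' endpoints; that maximum equals the trace term of the equivalence
#' theorem, which certifies G-optimality.
#'
#' @param spec A [random_slope_spec()].
#' @param w_star,w_mu Optimal design and measure weights.
#' @param x Evaluation points.
#' @export
random_slope_sensitivity <- function(spec,
                                     w_star = random_slope_weight(spec),
                                     w_mu = random_slope_mu_weight(spec, w_star),
                                     x) {
  n <- spec$n; delta <- spec$delta
  ((w_star^2 - 2 * w_star * w_mu + w_mu) / (w_star^2 * (w_star - 1)^2) +
     delta^2 * w_mu * (n - 1) / (delta * w_star + 1)^2) * x^2 +
    2 * (w_mu - 1) / (w_star - 1)^2 * x +
    (1 - w_mu) / (w_star - 1)^2
}

#' Design-free G-criterion value for random-intercept models
#'
#' When only the intercept is random (\eqn{D = d e_1 e_1^T} with
#' \eqn{f_1 \equiv 1}), the G-criterion lower bound collapses to
#' \eqn{p + (n-1)\delta/(1+\delta)}, independent of the design, and is
#' attained by the fixed-effects D-optimal design -- hence D- and
#' G-optimal designs coincide for such models.
#'
#' @param p Number of regression functions.
#' @param n Number of individuals.
#' @param delta \eqn{\delta = m d}.
#' @export
random_intercept_g_bound <- function(p, n, delta) {
  stopifnot(delta >= 0)
  p + (n - 1) * delta / (1 + delta)
}
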