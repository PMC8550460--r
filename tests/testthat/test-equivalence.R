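test_that("the measure moment matrix matches direct summation", {
  b <- factor_basis(1)
  # point mass
  m1 <- ma_matrix(design(0.4, 1), b)
  f <- c(1, 0.4)
  expect_equal(m1, f %o% f, ignore_attr = TRUE)
  # uniform on {0, 1} with basis (1, x)
  m2 <- ma_matrix(design(c(0, 1), c(0.5, 0.5)), b)
  expect_equal(m2, rbind(c(1, 0.5), c(0.5, 0.5)), ignore_attr = TRUE)
  # shares its oracle with the information matrix
  mod <- table_models()$quad_diag
  d <- printed_g_designs()$quad_diag
  expect_equal(ma_matrix(d, quad_basis), information_matrix(d, mod))
})

test_that("sensitivity_g matches the random-slope closed form", {
  spec <- random_slope_spec(10, 5, 0.2)
  mod <- random_slope_model(spec)
  ws <- random_slope_weight(spec)
  wmu <- random_slope_mu_weight(spec, ws)
  d <- design(c(0, 1), c(1 - ws, ws))
  mu <- design(c(0, 1), c(1 - wmu, wmu))
  xs <- seq(0, 1, by = 0.1)
  closed <- random_slope_sensitivity(spec, ws, wmu, xs) -
    (1 - wmu) / (ws - 1)^2             # closed form minus its max value
  expect_equal(sensitivity_g(d, mod, mu, xs), closed, tolerance = 1e-8)
  # roots at the support points of the optimal design
  expect_equal(sensitivity_g(d, mod, mu, c(0, 1)), c(0, 0),
               tolerance = 1e-8)
})

test_that("D = 0 sensitivity vanishes on the D-optimal support", {
  # quadratic on [1, 3]: equal weights at {1, 2, 3} are D-optimal, and
  # with mu concentrated there the G-sensitivity has roots at them
  mod <- hlm_model(quad_basis, matrix(0, 3, 3), n = 10, m = 1,
                   space = design_space(1, 3))
  d <- design(c(1, 2, 3), rep(1 / 3, 3))
  mu <- find_mu(d, mod)
  s <- sensitivity_g(d, mod, mu, c(1, 2, 3))
  expect_lt(max(abs(s)), 1e-6)
  xs <- seq(1, 3, by = 0.01)
  expect_lt(max(sensitivity_g(d, mod, mu, xs)), 1e-6)
})

test_that("measure_loss is nonnegative and prefers the right measure", {
  spec <- random_slope_spec(10, 5, 0.2)
  mod <- random_slope_model(spec)
  ws <- random_slope_weight(spec)
  wmu <- random_slope_mu_weight(spec, ws)
  d <- design(c(0, 1), c(1 - ws, ws))
  good <- design(c(0, 1), c(1 - wmu, wmu))
  bad <- design(c(0, 1), c(0.5, 0.5))
  expect_lt(measure_loss(d, mod, good), 1e-10)
  expect_lt(measure_loss(d, mod, good, "full"), 1e-5)
  expect_gt(measure_loss(d, mod, bad), measure_loss(d, mod, good))
  expect_gte(measure_loss(d, mod, bad), 0)
})

test_that("the answering set of the random-slope design is {0, 1}", {
  spec <- random_slope_spec(10, 5, 0.2)
  mod <- random_slope_model(spec)
  ws <- random_slope_weight(spec)
  d <- design(c(0, 1), c(1 - ws, ws))
  A <- answering_set(d, mod)
  expect_equal(nrow(A), 2)
  expect_equal(sort(A$x1), c(0, 1), tolerance = 1e-6)
})

test_that("a strictly concave variance function yields a singleton", {
  # one-point design for (1, x): phi is maximized at one end only
  mod <- hlm_model(factor_basis(1), diag(c(0.1, 0.1)), n = 4, m = 2,
                   space = design_space(0, 1))
  d <- design(c(0.2, 0.4), c(0.5, 0.5))
  A <- answering_set(d, mod)
  expect_equal(nrow(A), 1)
})

test_that("find_mu recovers the closed-form measure weight", {
  spec <- random_slope_spec(10, 5, 0.2)
  mod <- random_slope_model(spec)
  ws <- random_slope_weight(spec)
  d <- design(c(0, 1), c(1 - ws, ws))
  set.seed(99)
  mu <- find_mu(d, mod)
  wmu <- random_slope_mu_weight(spec, ws)
  got <- mu$weight[order(mu$x1)]
  expect_equal(got, c(1 - wmu, wmu), tolerance = 1e-3)
  # single-point answering set gives a point mass
  mod1 <- hlm_model(factor_basis(1), diag(c(0.1, 0.1)), n = 4, m = 2,
                    space = design_space(0, 1))
  d1 <- design(c(0.2, 0.4), c(0.5, 0.5))
  mu1 <- find_mu(d1, mod1)
  expect_equal(nrow(mu1), 1)
  expect_equal(mu1$weight, 1)
})

test_that("certification passes optimal designs and rejects perturbations", {
  spec <- random_slope_spec(10, 5, 0.2)
  mod <- random_slope_model(spec)
  ws <- random_slope_weight(spec)
  set.seed(42)
  rep_ok <- verify_g_optimality(design(c(0, 1), c(1 - ws, ws)), mod)
  expect_true(rep_ok$pass)
  expect_lt(max(abs(rep_ok$support_residuals)), rep_ok$threshold)
  rep_bad <- verify_g_optimality(design(c(0, 1), c(1 - ws + 0.08, ws - 0.08)),
                                 mod)
  expect_false(rep_bad$pass)
})

test_that("fixed-effects D-optimal quadratic passes the G certificate", {
  mod <- hlm_model(quad_basis, matrix(0, 3, 3), n = 10, m = 1,
                   space = design_space(1, 3))
  d <- design(c(1, 2, 3), rep(1 / 3, 3))
  set.seed(7)
  rep <- verify_g_optimality(d, mod)
  expect_true(rep$pass)
  expect_equal(rep$phi_bar, 3, tolerance = 1e-8)
})

test_that("fixed-effects D-sensitivity is nonpositive for the D-optimum", {
  mod <- hlm_model(quad_basis, matrix(0, 3, 3), n = 1, m = 1,
                   space = design_space(1, 3))
  d <- design(c(1, 2, 3), rep(1 / 3, 3))
  xs <- seq(1, 3, by = 0.002)
  expect_lt(max(sensitivity_d_fixed(d, mod, xs)), 1e-8)
  expect_equal(sensitivity_d_fixed(d, mod, c(1, 2, 3)), rep(0, 3),
               tolerance = 1e-10)
  # balanced two-point design for (1, x) on [0, 1]
  mod2 <- hlm_model(factor_basis(1), matrix(0, 2, 2), n = 1, m = 1,
                    space = design_space(0, 1))
  d2 <- design(c(0, 1), c(0.5, 0.5))
  expect_equal(sensitivity_d_fixed(d2, mod2, c(0, 1)), c(0, 0),
               tolerance = 1e-12)
})

test_that("the Atwood bound is sane, monotone, and guards its domain", {
  expect_equal(d_efficiency_lower_bound(4, 4), 1)
  expect_gt(d_efficiency_lower_bound(4, 4.2),
            d_efficiency_lower_bound(4, 4.5))
  expect_error(d_efficiency_lower_bound(4, 3.9), "impossible")
})
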