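test_that("information matrix matches direct summation", {
  mod <- hlm_model(factor_basis(1), diag(c(0, 0)), n = 2, m = 1,
                   space = design_space(0, 1))
  d <- design(c(0, 1), c(0.5, 0.5))
  expect_equal(information_matrix(d, mod),
               rbind(c(1, 0.5), c(0.5, 0.5)), ignore_attr = TRUE)
  # single-point design gives a rank-1 matrix
  mods <- table_models()$quad_diag
  d1 <- design(1.3, 1)
  expect_equal(qr(information_matrix(d1, mods))$rank, 1)
  # brute-force oracle on the printed three-point design
  dp <- printed_g_designs()$quad_diag
  M <- matrix(0, 3, 3)
  for (l in 1:3) {
    f <- c(1, dp$x1[l], dp$x1[l]^2)
    M <- M + dp$weight[l] * f %o% f
  }
  expect_equal(information_matrix(dp, mods), M, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("N(xi, Delta) handles singular D and matches the inverse form", {
  # D = 0 gives N = 0
  mod0 <- hlm_model(quad_basis, matrix(0, 3, 3), n = 5, m = 2,
                    space = design_space(0, 2))
  d <- design(c(0, 1, 2), rep(1 / 3, 3))
  expect_equal(n_matrix(d, mod0), matrix(0, 3, 3), ignore_attr = TRUE)
  # nonsingular D: Delta-form equals (M + Delta^{-1})^{-1}
  for (seed in 1:10) {
    mod <- random_hlm(seed, d_scale = 0.4)
    dd <- random_design(mod, seed = seed + 100)
    if (rank_psd(mod$D) < mod$p) next
    N1 <- n_matrix(dd, mod)
    M <- information_matrix(dd, mod)
    N2 <- solve(M + solve(mod$Delta))
    expect_equal(N1, N2, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("random-intercept N reduces to the scalar shrinkage form", {
  # D = delta e1 e1' with f1 = 1: Sherman-Morrison collapses N to the
  # single entry N11 = delta / (1 + delta e1' M e1), all else zero
  mod <- hlm_model(quad_basis, diag(c(1, 0, 0)), n = 6, m = 1,
                   space = design_space(1, 3))
  d <- design(c(1, 2, 3), rep(1 / 3, 3))
  N <- n_matrix(d, mod)
  M <- information_matrix(d, mod)
  expect_equal(N[1, 1], 1 / (1 + M[1, 1]), tolerance = 1e-10)
  expect_equal(N[2:3, ], matrix(0, 2, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("MSE matrix has the Kronecker block eigenstructure", {
  mod <- table_models()$quad_diag
  d <- printed_g_designs()$quad_diag
  mse <- mse_matrix(d, mod)
  s <- mod$sigma2 / mod$m
  ev_full <- sort(eigen(mse$full, symmetric = TRUE, only.values = TRUE)$values)
  ev_blocks <- sort(c(eigen(s * mse$Minv, TRUE, TRUE)$values,
                      rep(eigen(s * mse$N, TRUE, TRUE)$values, mod$n - 1)))
  expect_equal(ev_full, ev_blocks, tolerance = 1e-8)
  # n = 1: the deviation block vanishes and MSE = (sigma2/m) M^{-1}
  mod1 <- hlm_model(quad_basis, diag(c(0.2, 0.2, 0.3)), n = 1, m = 5,
                    space = design_space(0, 2))
  mse1 <- mse_matrix(d, mod1)
  expect_equal(mse1$full, (1 / 5) * mse1$Minv, tolerance = 1e-10,
               ignore_attr = TRUE)
  # D = 0: MSE is block-averaged with zero N-block
  mod0 <- hlm_model(quad_basis, matrix(0, 3, 3), n = 4, m = 5,
                    space = design_space(0, 2))
  mse0 <- mse_matrix(d, mod0)
  expect_equal(mse0$N, matrix(0, 3, 3), ignore_attr = TRUE)
})

test_that("phi reduces to the fixed-effects variance function at D = 0", {
  mod <- hlm_model(factor_basis(1), matrix(0, 2, 2), n = 7, m = 3,
                   space = design_space(0, 1))
  d <- design(c(0, 1), c(0.5, 0.5))
  expect_equal(phi(d, mod, 0), 2)
  expect_equal(phi(d, mod, 1), 2)
  expect_error(phi(d, mod, 1.5), "outside")
})

test_that("phi agrees with the random-slope closed form on a grid", {
  spec <- random_slope_spec(n = 10, m = 5, d = 0.2)
  mod <- random_slope_model(spec)
  w <- random_slope_weight(spec)
  d <- design(c(0, 1), c(1 - w, w))
  xs <- seq(0, 1, by = 0.05)
  expect_equal(phi(d, mod, xs), random_slope_phi(spec, w, xs),
               tolerance = 1e-10)
})

test_that("the G-criterion dominates its lower bound on random problems", {
  for (seed in 1:30) {
    mod <- random_hlm(seed)
    d <- random_design(mod, seed = seed + 500)
    g <- g_criterion(d, mod, grid_n = 401)$value
    expect_gte(g, g_lower_bound(d, mod) - 1e-8)
  }
})

test_that("the lower bound has its closed forms in special cases", {
  # D = 0: bound is p
  mod0 <- hlm_model(quad_basis, matrix(0, 3, 3), n = 10, m = 5,
                    space = design_space(0, 2))
  d <- design(c(0, 1, 2), rep(1 / 3, 3))
  expect_equal(g_lower_bound(d, mod0), 3)
  # random intercept: p + (n-1) delta / (1 + delta), free of the design
  modri <- hlm_model(factor_basis(1), diag(c(1, 0)), n = 10, m = 1,
                     space = design_space(0, 1))
  d2 <- design(c(0, 1), c(0.5, 0.5))
  d3 <- design(c(0.2, 0.9), c(0.3, 0.7))
  expect_equal(g_lower_bound(d2, modri), 2 + 9 * 0.5, tolerance = 1e-9)
  expect_equal(g_lower_bound(d3, modri), g_lower_bound(d2, modri),
               tolerance = 1e-9)
  expect_equal(random_intercept_g_bound(2, 10, 1), 6.5)
  expect_equal(random_intercept_g_bound(3, 10, 1), 7.5)
})

test_that("integrating phi against the design recovers the trace identity", {
  # sum_l w_l phi(x_l, xi) = p + (n-1) tr(N M)
  for (seed in 1:30) {
    mod <- random_hlm(seed)
    d <- random_design(mod, seed = seed + 900)
    lhs <- sum(d$weight * phi(d, mod, design_points(d)))
    M <- information_matrix(d, mod)
    N <- n_matrix(d, mod)
    rhs <- mod$p + (mod$n - 1) * sum(diag(N %*% M))
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("the prediction D-criterion reduces and errors as documented", {
  mod0 <- hlm_model(quad_basis, matrix(0, 3, 3), n = 10, m = 5,
                    space = design_space(0, 2))
  d <- design(c(0, 1, 2), rep(1 / 3, 3))
  expect_equal(d_pred_criterion(d, mod0)$value,
               -determinant(information_matrix(d, mod0))$modulus[1] / 5,
               ignore_attr = TRUE)
  # degenerate: two-point design cannot support q = 3 positive eigenvalues
  mod <- table_models()$quad_diag
  d2 <- design(c(0, 2), c(0.5, 0.5))
  expect_error(d_pred_criterion(d2, mod), "Degenerate|singular")
})

test_that("psi_D matches the eigenvalues of the scaled MSE matrix", {
  # exp(m * psi_D) equals the product of the (n-1)q + p largest
  # eigenvalues of m * MSE / sigma^2 for nonsingular D
  for (seed in c(2, 5, 8)) {
    mod <- random_hlm(seed, d_scale = 0.5)
    if (rank_psd(mod$D) < mod$p) next
    d <- random_design(mod, seed = seed + 70)
    mse <- mse_matrix(d, mod)
    ev <- sort(eigen(mod$m * mse$full / mod$sigma2, TRUE, TRUE)$values,
               decreasing = TRUE)
    nq <- (mod$n - 1) * mod$q + mod$p
    expect_equal(d_pred_criterion(d, mod)$value * mod$m,
                 sum(log(ev[seq_len(nq)])), tolerance = 1e-6)
  }
})

test_that("BLUP shrinks between population and individual estimates", {
  set.seed(7)
  m <- 6; n <- 9
  settings <- seq(0.1, 2, length.out = m)
  mod_base <- function(D) {
    hlm_model(quad_basis, D, n = n, m = m, space = design_space(0, 2))
  }
  Y <- matrix(rnorm(n * m, mean = 2), n, m)
  # D = 0: full shrinkage to the population estimate
  b0 <- blup(Y, mod_base(matrix(0, 3, 3)), settings)
  for (i in 1:n) {
    expect_equal(unname(b0$beta_i[i, ]), unname(b0$beta_hat),
                 tolerance = 1e-10)
  }
  # D -> infinity: no shrinkage (individual least squares)
  bi <- blup(Y, mod_base(1e8 * diag(3)), settings)
  Fm <- cbind(1, settings, settings^2)
  ind <- Y %*% Fm %*% solve(crossprod(Fm))
  expect_equal(bi$beta_i, ind, tolerance = 1e-5, ignore_attr = TRUE)
  # algebraic identity: the average of the predictors is the BLUE
  bmid <- blup(Y, mod_base(0.5 * diag(3)), settings)
  expect_equal(colMeans(bmid$beta_i), bmid$beta_hat, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("efficiencies behave as ratios should", {
  mod <- table_models()$quad_diag
  a <- printed_g_designs()$quad_diag
  b <- printed_d_designs()$quad_diag
  expect_equal(d_efficiency_fixed(a, a, mod), 1)
  expect_equal(d_efficiency_fixed(a, b, mod) * d_efficiency_fixed(b, a, mod),
               1, tolerance = 1e-10)
  # duplicated-point comparison against the determinant oracle
  a2 <- design(c(0, 0.966, 0.966, 2), c(0.146, 0.07, 0.07, 0.714))
  expect_equal(d_efficiency_fixed(a2, a, mod), 1, tolerance = 1e-10)
  expect_equal(pred_efficiency(a, a, mod, "G"), 1)
  expect_equal(pred_efficiency(a, a, mod, "D"), 1)
  # perturbing weights away from the optimum lowers efficiency
  worse <- design(c(0, 0.946, 2), c(0.29, 0.21, 0.50))
  expect_lt(pred_efficiency(worse, b, mod, "D"), 1)
  expect_lt(pred_efficiency(worse, b, mod, "D"),
            pred_efficiency(a, b, mod, "D"))
})

test_that("criterion evaluations tidy into exportable rows", {
  mod <- table_models()$quad_diag
  d <- printed_g_designs()$quad_diag
  tg <- tidy(g_criterion(d, mod))
  expect_named(tg, c("criterion", "value", "argmax_x1"))
  expect_equal(tg$criterion, "G_pred")
  td <- tidy(d_pred_criterion(d, mod))
  expect_named(td, c("criterion", "value"))
})

test_that("criteria are invariant to support permutation and duplication", {
  mod <- table_models()$fp_diag
  d <- printed_g_designs()$fp_diag
  perm <- design(design_points(d)[4:1, , drop = FALSE], d$weight[4:1])
  expect_equal(g_criterion(d, mod)$value, g_criterion(perm, mod)$value,
               tolerance = 1e-10)
  expect_equal(d_pred_criterion(d, mod)$value,
               d_pred_criterion(perm, mod)$value, tolerance = 1e-10)
  dup <- design(c(1, 1.440, 2.342, 3, 3),
                c(0.186, 0.190, 0.120, 0.3, 0.204))
  dup <- normalize_design(dup, mod$space)
  expect_equal(g_criterion(dup, mod)$value, g_criterion(d, mod)$value,
               tolerance = 1e-10)
})
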