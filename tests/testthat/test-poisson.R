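test_that("quasi-information reduces to the Poisson GLM information", {
  b <- factor_basis(2, interactions = list(c(1, 2)))
  sp <- design_space(c(-1, -1), c(1, 1))
  beta <- c(0.2, -0.4, 0.3, 0.1)
  mod0 <- poisson_model(b, beta, matrix(0, 4, 4), sp)
  # single point, weight one
  x <- c(0.3, -0.5)
  f <- basis_eval(b, x)
  lam <- exp(sum(f * beta))
  expect_equal(quasi_information(design(matrix(x, 1), 1), mod0),
               lam * f %o% f, ignore_attr = TRUE, tolerance = 1e-12)
  # several points: matches the weighted GLM sum
  d <- design(rbind(c(-1, -1), c(0, 0.5), c(1, -0.2), c(0.7, 1)),
              c(0.3, 0.25, 0.25, 0.2))
  Fm <- basis_matrix(b, design_points(d))
  lamv <- exp(drop(Fm %*% beta))
  expect_equal(quasi_information(d, mod0),
               crossprod(Fm, d$weight * lamv * Fm),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("random effects shrink the information", {
  b <- factor_basis(2, interactions = list(c(1, 2)))
  sp <- design_space(c(-1, -1), c(1, 1))
  beta <- c(0.2, -0.4, 0.3, 0.1)
  D <- diag(c(0.3, 0.2, 0.5, 0.6))
  d <- design(rbind(c(-1, -1), c(0, 0.5), c(1, -0.2), c(0.7, 1)),
              c(0.3, 0.25, 0.25, 0.2))
  M0 <- quasi_information(d, poisson_model(b, beta, matrix(0, 4, 4), sp))
  M1 <- quasi_information(d, poisson_model(b, beta, D, sp))
  # determinant cannot grow when within-individual correlation is added
  expect_lt(determinant(M1)$modulus[1], determinant(M0)$modulus[1])
  ev <- eigen(M1, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("the log-determinant criterion is permutation invariant", {
  mod <- poisson_uncorr()
  d <- poisson_uncorr_design()
  perm <- design(design_points(d)[5:1, ], d$weight[5:1])
  expect_equal(d_criterion_poisson(d, mod), d_criterion_poisson(perm, mod),
               tolerance = 1e-10)
  # duplicating a support point and renormalizing leaves it unchanged
  dup <- design(rbind(design_points(d), design_points(d)[1, , drop = FALSE]),
                c(d$weight[1] / 2, d$weight[-1], d$weight[1] / 2))
  dup <- normalize_design(dup, mod$space)
  expect_equal(d_criterion_poisson(dup, mod), d_criterion_poisson(d, mod),
               tolerance = 1e-8)
})

test_that("zero-variance coefficients require zero covariances", {
  b <- factor_basis(2, interactions = list(c(1, 2)))
  D_bad <- rbind(c(0.3, 0, 0, 0.1), c(0, 0.2, 0, 0),
                 c(0, 0, 0.5, 0), c(0.1, 0, 0, 0))
  expect_error(poisson_model(b, rep(0, 4), D_bad,
                             design_space(c(-1, -1), c(1, 1))),
               "zero covariances|positive semi-definite")
})

test_that("overflowing intensities raise a named error", {
  b <- factor_basis(1)
  mod <- poisson_model(b, c(0, 60), matrix(0, 2, 2), design_space(0, 1))
  expect_error(quasi_information(design(c(0, 1), c(0.5, 0.5)), mod),
               "support point 2")
})

test_that("the sensitivity is flat at p on the certified design", {
  mod <- poisson_uncorr()
  d <- poisson_uncorr_design()
  s <- sensitivity_poisson(d, mod, design_points(d))
  # printed three-decimal design: equality only to that precision
  expect_equal(s, rep(4, 5), tolerance = 0.01)
  best <- -Inf
  xs <- as.matrix(expand.grid(seq(-0.5, 1.7, length.out = 61),
                              seq(-1, 0.6, length.out = 61)))
  expect_lt(max(sensitivity_poisson(d, mod, xs)), 4 + 0.05)
})

test_that("D = 0 sensitivity is the weighted GLM variance function", {
  b <- factor_basis(1)
  sp <- design_space(0, 1)
  beta <- c(0.1, -1)
  mod <- poisson_model(b, beta, matrix(0, 2, 2), sp)
  d <- design(c(0, 1), c(0.4, 0.6))
  Fm <- basis_matrix(b, design_points(d))
  lam <- exp(drop(Fm %*% beta))
  M <- crossprod(Fm, d$weight * lam * Fm)
  xs <- matrix(seq(0, 1, by = 0.1), ncol = 1)
  Fx <- basis_matrix(b, xs)
  lamx <- exp(drop(Fx %*% beta))
  expected <- lamx * rowSums((Fx %*% solve(M)) * Fx)
  expect_equal(sensitivity_poisson(d, mod, xs), expected,
               tolerance = 1e-10)
})

test_that("D = 0 optima match a brute-force weight search", {
  # one-factor Poisson GLM, basis (1, x): enumerate two-point designs
  b <- factor_basis(1)
  sp <- design_space(0, 1)
  beta <- c(0, 1.2)
  mod <- poisson_model(b, beta, matrix(0, 2, 2), sp)
  # closed form for two points {a, b} with weight w at b:
  #   log|M| = log(w(1-w)) + beta2 (a + b) + 2 log(b - a),
  # enumerated over a dense grid as an independent oracle
  pts <- seq(0, 1, by = 0.0025)
  ws <- seq(0.0025, 0.9975, by = 0.0025)
  grid <- expand.grid(a = pts, b = pts)
  grid <- grid[grid$b > grid$a, ]
  best_w <- max(log(ws * (1 - ws)))
  best <- max(best_w + 1.2 * (grid$a + grid$b) + 2 * log(grid$b - grid$a))
  fit <- find_locally_d_optimal_poisson(mod, k = 3,
                                        config = quick_cso(max_iter = 150),
                                        restarts = 2, seed = 3)
  expect_gte(fit$value, best - 0.005)
  expect_equal(fit$efficiency_bound, 1, tolerance = 0.02)
})

test_that("the optimizer recovers the printed two-factor design", {
  mod <- poisson_uncorr()
  fit <- find_locally_d_optimal_poisson(mod, k = 6,
                                        config = cso_config(swarm = 128,
                                                            max_iter = 350),
                                        restarts = 2, seed = 1)
  expect_gte(fit$value, -2.67)
  expect_gte(nrow(fit$design), 5)
  expect_gte(fit$efficiency_bound, 0.95)
  # beating a random design of the same support size
  rd <- random_design(mod, k = nrow(fit$design), seed = 8)
  expect_gt(fit$value, d_criterion_poisson(rd, mod))
})
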