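# Shared fixtures: the worked-example models and printed designs used
# across the criterion and acceptance tests.

# run every file to the end even when several published-value checks
# disagree with the source tables (those discrepancies are asserted,
# not skipped)
options(testthat.progress.max_fails = 500)

quad_basis <- poly_basis(2)
fp4_basis <- fp_basis(c(0.5, 1, 2))

D_corr3 <- rbind(c(0.80, 0.30, 0.10),
                 c(0.30, 0.50, 0.08),
                 c(0.10, 0.08, 0.40))
D_corr4 <- rbind(c(0.80, 0.30, 0.10, 0.05),
                 c(0.30, 0.50, 0.08, 0.04),
                 c(0.10, 0.08, 0.40, 0.02),
                 c(0.05, 0.04, 0.02, 0.30))

table_models <- function() {
  list(
    quad_diag = hlm_model(quad_basis, diag(c(0.2, 0.2, 0.3)), n = 10, m = 5,
                          space = design_space(0, 2)),
    quad_corr = hlm_model(quad_basis, D_corr3, n = 11, m = 4,
                          space = design_space(0, 3)),
    fp_diag = hlm_model(fp4_basis, diag(c(0.3, 0.5, 0.8, 0.2)), n = 10,
                        m = 5, space = design_space(1, 3)),
    fp_corr = hlm_model(fp4_basis, D_corr4, n = 8, m = 4,
                        space = design_space(1, 3)),
    fp_corr_wide = hlm_model(fp4_basis, D_corr4, n = 10, m = 5,
                             space = design_space(1, 4))
  )
}

printed_g_designs <- function() {
  list(
    quad_diag = design(c(0, 0.966, 2), c(0.146, 0.140, 0.714)),
    quad_corr = design(c(0, 1.274, 3), c(0.165, 0.270, 0.565)),
    fp_diag = design(c(1, 1.440, 2.342, 3), c(0.186, 0.190, 0.120, 0.504)),
    fp_corr = design(c(1, 1.419, 2.372, 3), c(0.230, 0.186, 0.122, 0.462)),
    fp_corr_wide = design(c(1, 1.602, 2.914, 4),
                          c(0.206, 0.218, 0.109, 0.467))
  )
}

printed_d_designs <- function() {
  list(
    quad_diag = design(c(0, 0.946, 2), c(0.157, 0.140, 0.703)),
    quad_corr = design(c(0, 1.239, 3), c(0.163, 0.272, 0.565)),
    fp_diag = design(c(1, 1.412, 2.361, 3), c(0.230, 0.186, 0.122, 0.462)),
    fp_corr_wide = design(c(1, 1.599, 2.884, 4),
                          c(0.205, 0.217, 0.110, 0.468))
  )
}

# two-factor Poisson mixed model with an interaction, uncorrelated
# random effects, and its printed locally D-optimal design
poisson_uncorr <- function() {
  poisson_model(factor_basis(2, interactions = list(c(1, 2))),
                beta = c(-0.5, 0.2, -0.3, 0.4),
                D = diag(c(0.3, 0.2, 0.5, 0.6)),
                space = design_space(c(-0.5, -1.0), c(1.7, 0.6)))
}

poisson_uncorr_design <- function() {
  design(rbind(c(-0.5, -1.0), c(-0.5, 0.6), c(1.218, -1.0),
               c(1.7, -0.578), c(1.7, 0.6)),
         c(0.263, 0.382, 0.052, 0.144, 0.159))
}

poisson_corr <- function() {
  poisson_model(factor_basis(2, interactions = list(c(1, 2))),
                beta = c(-0.9, 1.0, 1.2, -1.5),
                D = rbind(c(0.30, 0.02, 0.10, 0),
                          c(0.02, 1.10, 0.60, 0),
                          c(0.10, 0.60, 1.20, 0),
                          c(0, 0, 0, 0)),
                space = design_space(c(-0.8, -1.3), c(1.4, 0.5)))
}

poisson_corr_design <- function() {
  design(rbind(c(-0.8, 0.5), c(0.528, -1.3), c(0.701, 0.5),
               c(1.179, -0.28), c(1.4, -1.3), c(1.4, 0.5)),
         c(0.365, 0.320, 0.135, 0.095, 0.075, 0.010))
}

# small swarm configuration for quick unit tests
quick_cso <- function(swarm = 32L, max_iter = 80L, ...) {
  cso_config(swarm = swarm, max_iter = max_iter, ...)
}
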