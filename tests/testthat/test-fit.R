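design <- default_study_design()

test_that("near-noiseless data are recovered to optimizer tolerance", {
  truth <- pk_parameters(ka_base = 0.289, ke_base = 0.0193,
                         factor_a = 1.06, slope_e = 0.175,
                         sigma2_add = 1e-8)
  spec <- model_spec(ka_covariate = "discrete", ke_covariate = "power",
                     error_model = "additive")
  dat <- simulate_dataset(simulation_config(design, truth, spec, seed = 11))
  fit <- fit_pk(dat, spec, design, init = truth, n_restarts = 0, compute_se = FALSE)
  expect_true(fit$converged)
  expect_equal(fit$par[["ka_base"]], 0.289, tolerance = 1e-3)
  expect_equal(fit$par[["ke_base"]], 0.0193, tolerance = 1e-3)
  expect_equal(fit$par[["factor_a"]], 1.06, tolerance = 1e-2)
  expect_equal(fit$par[["slope_e"]], 0.175, tolerance = 1e-2)
})

test_that("the fitted optimum is at least as good as the truth and stable under row order", {
  dat <- sim_final(seed = 21)
  spec <- final_spec()
  fit <- fit_pk(dat, spec, design, n_restarts = 2, seed = 1, compute_se = FALSE)
  expect_true(fit$converged)
  expect_lte(fit$ofv, neg2_loglik(final_truth(), spec, dat, design))
  set.seed(99)
  shuffled <- dat[sample(nrow(dat)), ]
  fit2 <- fit_pk(shuffled, spec, design, n_restarts = 2, seed = 1, compute_se = FALSE)
  expect_equal(fit2$ofv, fit$ofv, tolerance = 1e-6)
  expect_equal(fit2$par, fit$par, tolerance = 1e-3)
})

test_that("adding parameters never worsens the optimal objective", {
  dat <- sim_final(seed = 31, design = small_design())
  reduced_spec <- model_spec(error_model = "combined")
  full_spec <- final_spec()
  f_red <- fit_pk(dat, reduced_spec, design, n_restarts = 2, seed = 1,
                  compute_se = FALSE)
  init <- pk_parameters(ka_base = f_red$par[["ka_base"]],
                        ke_base = f_red$par[["ke_base"]],
                        factor_a = 0.05, slope_e = 0.05,
                        sigma2_prop = f_red$par[["sigma2_prop"]],
                        sigma2_add = f_red$par[["sigma2_add"]])
  f_full <- fit_pk(dat, full_spec, design, init = init, n_restarts = 2,
                   seed = 1, compute_se = FALSE)
  expect_lte(f_full$ofv, f_red$ofv + 1e-6)
})

test_that("standard errors shrink like 1/sqrt(n) with replication", {
  f_small <- fit_pk(sim_final(seed = 41, design = default_study_design(replicates = 3)),
                    final_spec(), default_study_design(replicates = 3),
                    n_restarts = 1, seed = 1)
  f_big <- fit_pk(sim_final(seed = 41, design = default_study_design(replicates = 12)),
                  final_spec(), default_study_design(replicates = 12),
                  n_restarts = 1, seed = 1)
  expect_true(f_small$cov_ok && f_big$cov_ok)
  ratio <- f_small$rse_percent[c("ka_base", "ke_base")] /
           f_big$rse_percent[c("ka_base", "ke_base")]
  # 4x the data should roughly halve the RSEs
  expect_true(all(ratio > 1.3 & ratio < 3.2))
})

test_that("curvature machinery is exact on a quadratic and flags indefinite Hessians", {
  # ofv(x) = 3 (x - 2)^2 has second derivative 6 -> covariance 2/6, SE = sqrt(1/3)
  H <- zfpk:::.hessian_cd(function(x) 3 * (x[1] - 2)^2, c(2))
  expect_equal(H[1, 1], 6, tolerance = 1e-6)
  cv <- zfpk:::.cov_from_hessian(H)
  expect_equal(sqrt(cv[1, 1]), sqrt(1 / 3), tolerance = 1e-6)
  expect_null(zfpk:::.cov_from_hessian(matrix(c(1, 0, 0, -1), 2)))
})

test_that("structural-parameter RSEs on study-design data are well below 20 percent", {
  fit <- fit_pk(sim_final(seed = 51), final_spec(), design, n_restarts = 2, seed = 1)
  expect_true(fit$cov_ok)
  expect_true(all(fit$rse_percent[c("ka_base", "factor_a", "ke_base", "slope_e")] < 20))
})

test_that("degenerate requests fail loudly", {
  dat <- sim_final(seed = 61)
  expect_error(fit_pk(dat[1:3, ], final_spec(), design),
               "at least as many observations")
})
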