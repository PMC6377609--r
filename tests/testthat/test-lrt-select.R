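design <- default_study_design()

# minimal hand-built fits for exercising the test arithmetic in isolation
fake_fit <- function(ofv, n_params, par_names, amounts = c(1, 2, 3)) {
  structure(list(ofv = ofv, n_params = n_params,
                 par = setNames(rep(1, n_params), par_names),
                 n_obs = length(amounts),
                 data = data.frame(amount_pmole = amounts)),
            class = "pk_fit")
}

test_that("LRT arithmetic: chi-squared reference, identity, clamping, nesting checks", {
  red <- fake_fit(100, 3, c("ka_base", "ke_base", "sigma2_add"))
  full <- fake_fit(100 - 6.635, 4, c("ka_base", "ke_base", "slope_e", "sigma2_add"))
  res <- lrt(red, full)
  expect_equal(res$statistic, 6.635)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, 0.01, tolerance = 1e-3)
  # identical objective -> no evidence for the extra parameter
  same <- fake_fit(100, 4, c("ka_base", "ke_base", "slope_e", "sigma2_add"))
  expect_equal(lrt(red, same)$p_value, 1)
  # numerically negative statistic is clamped with a warning
  worse <- fake_fit(100.5, 4, c("ka_base", "ke_base", "slope_e", "sigma2_add"))
  expect_warning(res2 <- lrt(red, worse), "clamped")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  # non-nested parameter sets and mismatched data are refused
  other <- fake_fit(90, 4, c("ka_base", "vmax", "km", "sigma2_add"))
  expect_error(lrt(red, other), "not nested")
  expect_error(lrt(red, fake_fit(90, 4, c("ka_base", "ke_base", "slope_e", "sigma2_add"),
                                 amounts = c(9, 9, 9))),
               "same dataset")
  expect_error(lrt(full, red), "more parameters")
})

test_that("selection recovers the generating covariate structure", {
  # data carry a strong age effect on both rates; the ladder should climb to
  # the discrete-ka + power-ke model in most replicates
  wins <- 0L
  for (s in 1:5) {
    dat <- sim_final(seed = 400 + s, design = small_design())
    sel <- select_model(dat, small_design(), default_model_ladder(),
                        alpha = 0.01, n_restarts = 1, seed = s)
    if (identical(sel$trace$candidate[max(which(sel$trace$accepted))],
                  "ka_discrete_ke_power")) wins <- wins + 1L
    expect_equal(nrow(sel$trace), 4L)
    expect_true(all(c("delta_ofv", "p_value", "accepted") %in% names(sel$trace)))
  }
  expect_gte(wins, 3L)
})

test_that("covariate extensions are rejected on age-homogeneous data", {
  # truth has no age effect: the covariate rungs should essentially never
  # clear the 1% hurdle
  truth <- pk_parameters(ka_base = 0.289, ke_base = 0.0193,
                         sigma2_prop = 0.109, sigma2_add = 0.00844)
  accepted <- 0L
  for (s in 1:8) {
    dat <- simulate_dataset(simulation_config(small_design(), truth,
                                              model_spec(), seed = 500 + s))
    sel <- select_model(dat, small_design(), default_model_ladder(),
                        alpha = 0.01, n_restarts = 1, seed = s)
    cov_rows <- sel$trace$candidate %in% c("ka_discrete", "ka_discrete_ke_power")
    accepted <- accepted + sum(sel$trace$accepted[cov_rows])
  }
  expect_lte(accepted, 2L)
})

test_that("a single-candidate ladder returns that candidate", {
  dat <- sim_final(seed = 71, design = small_design())
  sel <- select_model(dat, small_design(), list(only = final_spec()),
                      n_restarts = 1, seed = 1)
  expect_identical(sel$spec, final_spec())
  expect_equal(nrow(sel$trace), 1L)
  expect_true(sel$trace$accepted)
  expect_error(select_model(dat, small_design(), list()), "at least one")
})
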