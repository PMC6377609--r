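design <- default_study_design()

test_that("constant-treatment closed form starts at zero and plateaus at ka/ke", {
  p <- pk_parameters(ka_base = 0.289, ke_base = 0.0193)
  m <- model_spec()
  expect_equal(predict_amount(p, m, 3, "constant", 0, design), 0)
  plateau <- predict_amount(p, m, 3, "constant", 1e5, design)
  expect_equal(plateau, 0.289 / 0.0193, tolerance = 1e-10)
  expect_error(predict_amount(p, m, 3, "constant", -5, design), "non-negative")
})

test_that("closed form agrees with ODE integration at random parameters and times", {
  m <- final_spec()
  set.seed(101)
  for (i in 1:50) {
    p <- random_params()
    age <- sample(3:5, 1)
    arm <- sample(c("constant", "washout"), 1)
    t <- runif(1, 1, if (arm == "constant") 180 else 240)
    cf <- predict_amount(p, m, age, arm, t, design, method = "closed_form")
    od <- predict_amount(p, m, age, arm, t, design, method = "ode")
    expect_equal(od, cf, tolerance = 1e-6)
  }
})

test_that("amount is monotone up under treatment, monotone down after washout, continuous at the switch", {
  p <- final_truth()
  m <- final_spec()
  tt <- seq(0, 240, by = 1)
  for (age in 3:5) {
    up <- predict_amount(p, m, age, "constant", tt[tt <= 180], design)
    expect_true(all(diff(up) >= 0))
    wo <- predict_amount(p, m, age, "washout", tt, design)
    expect_true(all(diff(wo[tt >= 60]) <= 0))
    # continuity at the treatment/washout junction
    eps <- 1e-6
    left <- predict_amount(p, m, age, "washout", 60 - eps, design)
    right <- predict_amount(p, m, age, "washout", 60 + eps, design)
    expect_equal(left, right, tolerance = 1e-4)
  }
})

test_that("two-compartment model with no exchange collapses to one compartment", {
  p1 <- pk_parameters(ka_base = 0.3, ke_base = 0.02)
  p2 <- pk_parameters(ka_base = 0.3, ke_base = 0.02, k12 = 0, k21 = 0)
  m1 <- model_spec()
  m2 <- model_spec(n_compartments = 2)
  tt <- c(15, 60, 120, 180)
  for (arm in c("constant", "washout")) {
    expect_equal(predict_amount(p2, m2, 3, arm, tt, design),
                 predict_amount(p1, m1, 3, arm, tt, design),
                 tolerance = 1e-6)
  }
})

test_that("two-compartment prediction is the sum of both compartment amounts", {
  # with exchange on, the total exceeds what the eliminating compartment
  # alone would hold late in washout (drug parked peripherally returns)
  p <- pk_parameters(ka_base = 0.3, ke_base = 0.05, k12 = 0.05, k21 = 0.01)
  m2 <- model_spec(n_compartments = 2)
  m1 <- model_spec()
  p1 <- pk_parameters(ka_base = 0.3, ke_base = 0.05)
  t_late <- 240
  expect_gt(predict_amount(p, m2, 3, "washout", t_late, design),
            predict_amount(p1, m1, 3, "washout", t_late, design))
})

test_that("Michaelis-Menten elimination linearises to first order when km >> A", {
  ke <- 0.0193
  km <- 1e6
  p_mm <- pk_parameters(ka_base = 0.289, ke_base = 0, vmax = ke * km, km = km)
  m_mm <- model_spec(elimination = "michaelis_menten")
  p_lin <- pk_parameters(ka_base = 0.289, ke_base = ke)
  m_lin <- model_spec()
  tt <- c(30, 60, 120, 180)
  expect_equal(predict_amount(p_mm, m_mm, 3, "constant", tt, design),
               predict_amount(p_lin, m_lin, 3, "constant", tt, design),
               tolerance = 1e-5)
  expect_error(predict_amount(pk_parameters(0.3, 0.02), m_mm, 3, "constant", 60, design),
               "vmax")
})

test_that("time to steady-state fraction follows -ln(1-f)/ke", {
  expect_equal(time_to_steady_state(0.0193, 0.9), log(10) / 0.0193)
  expect_equal(time_to_steady_state(0.0193, 1e-12), 0, tolerance = 1e-9)
  # doubling the elimination rate halves the time, at any fraction
  expect_equal(time_to_steady_state(0.04, 0.7),
               time_to_steady_state(0.02, 0.7) / 2)
  expect_error(time_to_steady_state(0.02, 1), "strictly between")
  expect_error(time_to_steady_state(0.02, 0), "strictly between")
})

test_that("clearance is ke * volume * 60 in nL/h", {
  expect_equal(clearance(0.0193, 253), 0.0193 * 253 * 60)
  expect_equal(clearance(0, 300), 0)
  expect_error(clearance(0.02, -1), "positive")
})
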