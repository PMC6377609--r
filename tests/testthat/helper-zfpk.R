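# Shared fixtures: the final larval model, its reported parameter values, and
# reduced designs that keep replicate fitting fast.

final_truth <- function() {
  pk_parameters(ka_base = 0.289, ke_base = 0.0193,
                factor_a = 1.06, slope_e = 0.175,
                sigma2_prop = 0.109, sigma2_add = 0.00844)
}

final_spec <- function() {
  model_spec(ka_covariate = "discrete", ke_covariate = "power",
             error_model = "combined")
}

# sparser sampling grid for simulation studies that need many refits
small_design <- function(replicates = 3L) {
  design_spec(ages = c(3L, 4L, 5L),
              treatment_times = c(30, 90, 180),
              washout_times = c(90, 150, 240),
              replicates = replicates)
}

sim_final <- function(seed, design = default_study_design(),
                      truth = final_truth(), spec = final_spec()) {
  simulate_dataset(simulation_config(design, truth, spec, seed = seed))
}

# random draw of plausible one-compartment parameters for property checks
random_params <- function() {
  pk_parameters(ka_base = runif(1, 0.05, 1),
                ke_base = runif(1, 0.005, 0.05),
                factor_a = runif(1, -0.5, 2),
                slope_e = runif(1, -0.3, 0.5),
                sigma2_prop = runif(1, 0.01, 0.2),
                sigma2_add = runif(1, 0.001, 0.05))
}
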