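#' Configuration of a synthetic-data simulation
#'
#' Bundles the experimental design, the true parameter values, the generating
#' model and the random seed into one reproducible simulation recipe: the
#' same configuration always yields the identical dataset.
#'
#' @param design a [design_spec()].
#' @param truth a [pk_parameters()] holding the generating values.
#' @param spec the generating [model_spec()].
#' @param seed integer random seed.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(design, truth, spec, seed) {
  stopifnot(inherits(design, "design_spec"), inherits(truth, "pk_parameters"),
            inherits(spec, "model_spec"))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(design = design, truth = truth, spec = spec,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a study-design-faithful dataset
#'
#' Generates one pooled-larvae measurement per (age, arm, time, replicate)
#' cell of the design. Observations follow the combined residual-error
#' composition
#' `obs = pred * (1 + e1) + e2` with `e1 ~ N(0, sigma2_prop)` and
#' `e2 ~ N(0, sigma2_add)` drawn independently per sample (noise acts at the
#' pooled-sample level: one lysed pool yields a single measurement, so the
#' pool size is metadata, not a variance divisor). Negative simulated amounts
#' are physically impossible and are truncated at zero; the number of
#' truncations is recorded in the `n_truncated` attribute and should be
#' negligible under realistic designs.
#'
#' @param config a [simulation_config()].
#' @return data frame with columns `sample_id`, `age_dpf`, `arm`, `time_min`,
#'   `amount_pmole`, `pool_size`, and attribute `n_truncated`.
#' @export
#' @examples
#' truth <- pk_parameters(0.289, 0.0193, factor_a = 1.06, slope_e = 0.175,
#'                        sigma2_prop = 0.109, sigma2_add = 0.00844)
#' spec <- model_spec(ka_covariate = "discrete", ke_covariate = "power")
#' dat <- simulate_dataset(simulation_config(default_study_design(), truth, spec, seed = 1))
#' head(dat)
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  design <- config$design
  grid <- do.call(rbind, lapply(design$ages, function(a) {
    rbind(
      data.frame(age_dpf = a, arm = "constant", time_min = design$treatment_times),
      data.frame(age_dpf = a, arm = "washout", time_min = design$washout_times)
    )
  }))
  grid <- grid[rep(seq_len(nrow(grid)), each = design$replicates), ]
  grid$replicate <- rep(seq_len(design$replicates), length.out = nrow(grid))
  rownames(grid) <- NULL

  pred <- .predict_obs(config$truth, config$spec, grid, design)
  .with_seed(config$seed, {
    e1 <- rnorm(nrow(grid), 0, sqrt(config$truth$sigma2_prop))
    e2 <- rnorm(nrow(grid), 0, sqrt(config$truth$sigma2_add))
    amount <- switch(config$spec$error_model,
      additive = pred + e2,
      proportional = pred * (1 + e1),
      combined = pred * (1 + e1) + e2
    )
    n_trunc <- sum(amount < 0)
    amount[amount < 0] <- 0
    out <- data.frame(
      sample_id = sprintf("a%d_%s_t%03d_r%d", grid$age_dpf,
                          substr(grid$arm, 1, 4), round(grid$time_min),
                          grid$replicate),
      age_dpf = grid$age_dpf,
      arm = grid$arm,
      time_min = grid$time_min,
      amount_pmole = amount,
      pool_size = design$pool_size,
      stringsAsFactors = FALSE
    )
    attr(out, "n_truncated") <- n_trunc
    out
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  print(x$design)
  print(x$spec)
  invisible(x)
}
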