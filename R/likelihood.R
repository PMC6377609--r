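# residual-error variance for each observation, by error-model form
.obs_variance <- function(pred, error_model, sigma2_prop, sigma2_add) {
  switch(error_model,
    additive = rep(sigma2_add, length(pred)),
    proportional = pred^2 * sigma2_prop,
    combined = pred^2 * sigma2_prop + sigma2_add,
    stop("unknown error model: ", error_model)
  )
}

# core of the objective: obs and matching predictions already in hand
.neg2_loglik_core <- function(obs, pred, error_model, sigma2_prop, sigma2_add) {
  v <- .obs_variance(pred, error_model, sigma2_prop, sigma2_add)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("degenerate residual-error model: non-positive observation variance")
  res <- obs - pred
  sum(log(2 * pi * v) + res^2 / v)
}

# prediction closure specialised to a fixed dataset; avoids per-evaluation
# validation and grouping inside the optimiser's inner loop
.make_predictor <- function(spec, data, design) {
  if (spec$n_compartments == 1L && spec$elimination == "first_order") {
    ages <- sort(unique(data$age_dpf))
    age_idx <- match(data$age_dpf, ages)
    t <- data$time_min
    washout <- data$arm == "washout"
    t_d <- design$treatment_duration_min
    function(params) {
      ka <- .ka_at(params, spec, ages)[age_idx]
      ke <- .ke_at(params, spec, ages)[age_idx]
      a_ss <- ka / ke
      up <- a_ss * (1 - exp(-ke * t))
      down <- a_ss * (1 - exp(-ke * t_d)) * exp(-ke * (t - t_d))
      ifelse(washout & t > t_d, down, up)
    }
  } else {
    function(params) .predict_obs(params, spec, data, design)
  }
}

#' Objective function value (-2 log-likelihood)
#'
#' Exact Gaussian likelihood with heteroscedastic residual variance. Per
#' observation the variance is `v_i = pred_i^2 * sigma2_prop + sigma2_add`
#' (with the proportional or additive term dropped under the pure error-model
#' forms), and the objective function value is
#' `sum_i [ log(2 pi v_i) + (obs_i - pred_i)^2 / v_i ]`.
#'
#' With no between-larva random effects (single observations per lysed pooled
#' sample), this fixed-effects extended-least-squares likelihood is the model
#' actually identified by the data.
#'
#' @param params a [pk_parameters()].
#' @param spec a [model_spec()].
#' @param data observation table as produced by [simulate_dataset()] or
#'   [read_pk_dataset()].
#' @param design a [design_spec()].
#' @return the objective function value (scalar).
#' @export
neg2_loglik <- function(params, spec, data, design) {
  data <- validate_pk_data(data)
  pred <- .predict_obs(params, spec, data, design)
  .neg2_loglik_core(data$amount_pmole, pred, spec$error_model,
                    params$sigma2_prop, params$sigma2_add)
}

#' Proportional-error coefficient of variation
#'
#' Expresses the variance of the proportional residual error as a coefficient
#' of variation in percent, `100 * sqrt(sigma2_prop)`.
#'
#' @param sigma2_prop variance of the proportional residual error, >= 0.
#' @return CV in percent.
#' @export
#' @examples
#' prop_error_cv(0.109)
prop_error_cv <- function(sigma2_prop) {
  stopifnot(is.numeric(sigma2_prop), all(sigma2_prop >= 0))
  100 * sqrt(sigma2_prop)
}
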