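#' Likelihood ratio test between two nested fits
#'
#' Compares a reduced and a full model fitted to the same dataset. The test
#' statistic is the drop in objective function value,
#' `OFV_reduced - OFV_full`, referred to a chi-squared distribution with
#' degrees of freedom equal to the difference in number of parameters. A
#' (numerically) negative statistic is clamped to zero with a warning.
#'
#' @param fit_reduced,fit_full [fit_pk()] results for the nested pair; the
#'   reduced model's free parameters must be a subset of the full model's.
#' @return object of class `pk_lrt`: list with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' \donttest{
#' design <- default_study_design()
#' truth <- pk_parameters(0.289, 0.0193, slope_e = 0.175,
#'                        sigma2_prop = 0.109, sigma2_add = 0.00844)
#' spec_full <- model_spec(ke_covariate = "power")
#' dat <- simulate_dataset(simulation_config(design, truth, spec_full, seed = 7))
#' f0 <- fit_pk(dat, model_spec(), design, n_restarts = 2, seed = 1)
#' f1 <- fit_pk(dat, spec_full, design, n_restarts = 2, seed = 1)
#' lrt(f0, f1)
#' }
lrt <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "pk_fit"), inherits(fit_full, "pk_fit"))
  if (fit_full$n_params <= fit_reduced$n_params)
    stop("'fit_full' must have more parameters than 'fit_reduced'")
  extra <- setdiff(names(fit_reduced$par), names(fit_full$par))
  if (length(extra))
    stop("models are not nested: reduced model has parameters absent from ",
         "the full model (", paste(extra, collapse = ", "), ")")
  if (fit_reduced$n_obs != fit_full$n_obs ||
      !isTRUE(all.equal(sort(fit_reduced$data$amount_pmole),
                        sort(fit_full$data$amount_pmole))))
    stop("the two fits were not obtained on the same dataset")
  stat <- fit_reduced$ofv - fit_full$ofv
  if (stat < 0) {
    warning("negative LRT statistic (", format(stat),
            ") clamped to zero; the full-model fit may not have converged ",
            "to its global optimum")
    stat <- 0
  }
  df <- fit_full$n_params - fit_reduced$n_params
  p <- if (stat == 0) 1 else pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p), class = "pk_lrt")
}

#' @export
print.pk_lrt <- function(x, ...) {
  cat("Likelihood ratio test: dOFV = ", format(x$statistic, digits = 5),
      ", df = ", x$df, ", p = ", format.pval(x$p_value, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Stepwise model selection over a ladder of nested candidates
#'
#' Walks a ladder of increasingly rich model specifications (structure, then
#' error model, then covariate forms), accepting each extension only when the
#' likelihood ratio test against the currently accepted model is significant
#' at `alpha`, the fit converged, and all relative standard errors are below
#' `rse_max` percent. A tie at the significance boundary keeps the reduced
#' model (parsimony). Each subsequent fit is warm-started from the currently
#' accepted estimates.
#'
#' @param data observation table.
#' @param design a [design_spec()].
#' @param ladder named list of [model_spec()]s ordered from simplest to
#'   richest; consecutive accepted models must be nested.
#' @param alpha significance level of the likelihood ratio test
#'   (default 0.01).
#' @param rse_max acceptance bound on relative standard errors, percent
#'   (default 50).
#' @param rse_scope parameters the RSE bound applies to: `"structural"`
#'   (default; rate constants and covariate coefficients) or `"all"`
#'   (additionally the residual-error variances). The additive variance
#'   component is only weakly identified when proportional noise dominates at
#'   every sampled amount, so under sparse designs an all-parameter gate can
#'   veto extensions the likelihood overwhelmingly supports.
#' @param n_restarts,seed passed to [fit_pk()].
#' @return list with `spec` (winning [model_spec()]), `fit` (its `pk_fit`),
#'   `trace` (data frame with one row per candidate: ofv, dOFV, df, p-value,
#'   RSE check, decision).
#' @seealso [default_model_ladder()]
#' @export
select_model <- function(data, design, ladder = default_model_ladder(),
                         alpha = 0.01, rse_max = 50,
                         rse_scope = c("structural", "all"),
                         n_restarts = 5L, seed = NULL) {
  rse_scope <- match.arg(rse_scope)
  if (length(ladder) == 0L) stop("'ladder' must contain at least one candidate")
  if (is.null(names(ladder)))
    names(ladder) <- paste0("candidate_", seq_along(ladder))

  rse_pass <- function(fit) {
    if (!fit$cov_ok) return(FALSE)
    rse <- fit$rse_percent
    if (rse_scope == "structural")
      rse <- rse[!names(rse) %in% c("sigma2_prop", "sigma2_add")]
    all(is.finite(rse)) && all(rse < rse_max)
  }

  current <- fit_pk(data, ladder[[1]], design, n_restarts = n_restarts, seed = seed)
  trace <- data.frame(
    candidate = names(ladder)[1], n_params = current$n_params,
    ofv = current$ofv, delta_ofv = NA_real_, df = NA_integer_,
    p_value = NA_real_, converged = current$converged,
    rse_ok = rse_pass(current),
    accepted = TRUE, stringsAsFactors = FALSE
  )
  if (length(ladder) == 1L)
    return(list(spec = ladder[[1]], fit = current, trace = trace))

  for (k in 2:length(ladder)) {
    cand_spec <- ladder[[k]]
    init <- .warm_init(current, cand_spec)
    cand <- fit_pk(data, cand_spec, design, init = init,
                   n_restarts = n_restarts, seed = seed)
    test <- withCallingHandlers(
      lrt(current, cand),
      warning = function(w) invokeRestart("muffleWarning")
    )
    rse_ok <- rse_pass(cand)
    accept <- cand$converged && rse_ok && test$p_value < alpha
    trace <- rbind(trace, data.frame(
      candidate = names(ladder)[k], n_params = cand$n_params,
      ofv = cand$ofv, delta_ofv = test$statistic, df = test$df,
      p_value = test$p_value, converged = cand$converged,
      rse_ok = rse_ok, accepted = accept, stringsAsFactors = FALSE
    ))
    if (accept) current <- cand
  }
  winner <- trace$candidate[max(which(trace$accepted))]
  list(spec = ladder[[winner]], fit = current, trace = trace)
}

# carry shared estimates from the accepted model into the next candidate's
# start; newly introduced parameters get small neutral values
.warm_init <- function(fit, spec) {
  nm <- .free_param_names(spec)
  theta <- setNames(numeric(length(nm)), nm)
  defaults <- c(factor_a = 0.05, slope_e = 0.05, sigma2_prop = 0.02,
                sigma2_add = 1e-3, k12 = 0.01, k21 = 0.01,
                vmax = NA_real_, km = NA_real_)
  for (n in nm) {
    theta[n] <- if (n %in% names(fit$par)) fit$par[[n]]
                else if (n %in% names(defaults)) defaults[[n]]
                else 0.01
  }
  if ("vmax" %in% nm && is.na(theta["vmax"]))
    theta["vmax"] <- fit$par[["ka_base"]]
  if ("km" %in% nm && is.na(theta["km"]))
    theta["km"] <- max(fit$data$amount_pmole)
  .params_from_free(theta, spec)
}

#' Default model-selection ladder
#'
#' The candidate sequence used for the larval paracetamol analysis: a
#' one-compartment model with zero-order absorption and first-order
#' elimination under an additive error model; extension to a combined
#' additive + proportional error model; then a discrete age covariate on the
#' absorption rate; then a power age covariate on the elimination rate.
#'
#' @return named list of [model_spec()]s.
#' @export
default_model_ladder <- function() {
  list(
    base_additive = model_spec(error_model = "additive"),
    combined_error = model_spec(error_model = "combined"),
    ka_discrete = model_spec(ka_covariate = "discrete", error_model = "combined"),
    ka_discrete_ke_power = model_spec(ka_covariate = "discrete",
                                      ke_covariate = "power",
                                      error_model = "combined")
  )
}
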