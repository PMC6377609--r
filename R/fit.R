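# ---- free-parameter bookkeeping -------------------------------------------
#
# Estimation works on a named vector of the parameters the model spec
# actually uses, optimised on a transformed scale: log for strictly positive
# quantities (rates, variances), log(1 + x) for the covariate coefficients so
# they stay above -1.

.free_param_names <- function(spec) {
  nm <- "ka_base"
  if (spec$ka_covariate != "none") nm <- c(nm, "factor_a")
  if (spec$elimination == "first_order") {
    nm <- c(nm, "ke_base")
    if (spec$ke_covariate != "none") nm <- c(nm, "slope_e")
  } else {
    nm <- c(nm, "vmax", "km")
  }
  if (spec$n_compartments == 2L) nm <- c(nm, "k12", "k21")
  nm <- c(nm, switch(spec$error_model,
    additive = "sigma2_add",
    proportional = "sigma2_prop",
    combined = c("sigma2_prop", "sigma2_add")
  ))
  nm
}

.transform_of <- function(names) {
  ifelse(names %in% c("factor_a", "slope_e"), "log1p", "log")
}

.to_est_scale <- function(theta) {
  tr <- .transform_of(names(theta))
  out <- ifelse(tr == "log1p", log1p(theta), log(theta))
  names(out) <- names(theta)
  out
}

.from_est_scale <- function(phi) {
  tr <- .transform_of(names(phi))
  out <- ifelse(tr == "log1p", expm1(phi), exp(phi))
  names(out) <- names(phi)
  out
}

# d(theta)/d(phi) evaluated at the optimum, for the delta method
.jacobian_diag <- function(theta) {
  tr <- .transform_of(names(theta))
  ifelse(tr == "log1p", 1 + theta, theta)
}

.params_from_free <- function(theta, spec) {
  full <- list(ka_base = NA_real_, ke_base = 0, factor_a = 0, slope_e = 0,
               sigma2_prop = 0, sigma2_add = 0,
               vmax = NA_real_, km = NA_real_, k12 = NA_real_, k21 = NA_real_)
  full[names(theta)] <- as.list(theta)
  do.call(pk_parameters, full)
}

.free_from_params <- function(params, spec) {
  nm <- .free_param_names(spec)
  vapply(nm, function(n) params[[n]], numeric(1))
}

# data-driven starting values: crude elimination rate from the washout
# log-decline at the reference age, absorption rate from the plateau level
.heuristic_init <- function(data, spec, design) {
  ref <- spec$reference_age
  sub <- data[data$age_dpf == ref, , drop = FALSE]
  if (nrow(sub) == 0L) sub <- data
  ke0 <- 0.01
  wo <- sub[sub$arm == "washout" & sub$amount_pmole > 0, , drop = FALSE]
  if (nrow(wo) >= 3L && length(unique(wo$time_min)) >= 2L) {
    sl <- unname(coef(lm(log(amount_pmole) ~ time_min, data = wo))[2])
    if (is.finite(sl) && sl < 0) ke0 <- -sl
  }
  co <- sub[sub$arm == "constant", , drop = FALSE]
  a_ss <- if (nrow(co)) median(co$amount_pmole[co$time_min >= 0.6 * max(co$time_min)])
          else median(sub$amount_pmole)
  if (!is.finite(a_ss) || a_ss <= 0) a_ss <- max(data$amount_pmole, 1)
  ka0 <- max(ke0 * a_ss, 1e-4)
  theta <- c(ka_base = ka0)
  if (spec$ka_covariate != "none") theta <- c(theta, factor_a = 0.2)
  if (spec$elimination == "first_order") {
    theta <- c(theta, ke_base = ke0)
    if (spec$ke_covariate != "none") theta <- c(theta, slope_e = 0.1)
  } else {
    theta <- c(theta, vmax = 2 * ke0 * a_ss, km = a_ss)
  }
  if (spec$n_compartments == 2L) theta <- c(theta, k12 = 0.01, k21 = 0.01)
  s2a0 <- max(0.05 * stats::var(data$amount_pmole), 1e-4)
  theta <- c(theta, switch(spec$error_model,
    additive = c(sigma2_add = s2a0),
    proportional = c(sigma2_prop = 0.05),
    combined = c(sigma2_prop = 0.05, sigma2_add = 0.25 * s2a0)
  ))
  theta[.free_param_names(spec)]
}

# run a block of code with its own RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Fit a pharmacokinetic model by maximum likelihood
#'
#' Minimises [neg2_loglik()] over the parameters used by `spec`, on a
#' log-transformed scale that enforces positivity (covariate coefficients are
#' bounded below at -1 via a `log(1 + x)` transform). A multi-start strategy
#' is used: the first start is `init` (or a data-driven heuristic), remaining
#' starts are log-normally jittered copies. Each start is polished with
#' Nelder-Mead followed by BFGS; the best converged optimum is returned,
#' together with standard errors from the curvature of the objective (see
#' [standard_errors()]).
#'
#' @param data observation table (see [read_pk_dataset()]).
#' @param spec a [model_spec()].
#' @param design a [design_spec()].
#' @param init optional [pk_parameters()] starting values; the fields the
#'   spec does not use are ignored.
#' @param n_restarts number of jittered restarts in addition to the primary
#'   start.
#' @param seed seed for the restart jitter (the fit itself is deterministic
#'   given data and starts).
#' @param compute_se compute the covariance/RSE step (default `TRUE`).
#' @return an object of class `pk_fit` with elements `estimates`
#'   ([pk_parameters()]), `par` (named vector of the free parameters), `ofv`,
#'   `covariance`, `se`, `rse_percent`, `converged`, `cov_ok`, `n_obs`,
#'   `n_params`, plus the spec, design and data used.
#' @export
#' @examples
#' design <- default_study_design()
#' truth <- pk_parameters(0.289, 0.0193, factor_a = 1.06, slope_e = 0.175,
#'                        sigma2_prop = 0.109, sigma2_add = 0.00844)
#' spec <- model_spec(ka_covariate = "discrete", ke_covariate = "power")
#' dat <- simulate_dataset(simulation_config(design, truth, spec, seed = 1))
#' fit <- fit_pk(dat, spec, design, n_restarts = 2, seed = 1)
#' fit
fit_pk <- function(data, spec, design, init = NULL,
                   n_restarts = 10L, seed = NULL, compute_se = TRUE) {
  data <- validate_pk_data(data, design)
  nm <- .free_param_names(spec)
  if (nrow(data) < length(nm))
    stop("need at least as many observations (", nrow(data),
         ") as free parameters (", length(nm), ")")

  theta0 <- if (is.null(init)) .heuristic_init(data, spec, design)
            else .free_from_params(init, spec)
  if (any(!is.finite(theta0)))
    stop("starting values must be finite for all free parameters: ",
         paste(nm[!is.finite(theta0)], collapse = ", "))
  theta0 <- pmax(theta0, 1e-8)  # log transforms need strictly positive starts
  phi0 <- .to_est_scale(theta0)

  predictor <- .make_predictor(spec, data, design)
  obs <- data$amount_pmole
  objective <- function(phi) {
    names(phi) <- nm
    val <- tryCatch({
      params <- .params_from_free(.from_est_scale(phi), spec)
      .neg2_loglik_core(obs, predictor(params), spec$error_model,
                        params$sigma2_prop, params$sigma2_add)
    }, error = function(e) Inf)
    if (!is.finite(val)) 1e12 else val
  }

  starts <- .with_seed(seed, {
    jitters <- replicate(max(n_restarts, 0L),
                         phi0 + rnorm(length(phi0), sd = 0.5),
                         simplify = FALSE)
    c(list(phi0), jitters)
  })

  best <- NULL
  for (i in seq_along(starts)) {
    o1 <- optim(starts[[i]], objective, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-10))
    o2 <- tryCatch(
      optim(o1$par, objective, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) o1
    )
    cand <- if (o2$value <= o1$value) o2 else o1
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (!is.finite(best$value) || best$value >= 1e12)
    stop("no start converged to a finite objective; best attempt: ",
         format(best$value), " with parameters ",
         paste(format(.from_est_scale(setNames(best$par, nm))), collapse = ", "))

  phi_hat <- setNames(best$par, nm)
  theta_hat <- .from_est_scale(phi_hat)
  estimates <- .params_from_free(theta_hat, spec)

  fit <- structure(
    list(estimates = estimates, par = theta_hat, est_par = phi_hat,
         ofv = best$value, converged = best$convergence == 0,
         covariance = NULL, se = NULL, rse_percent = NULL, cov_ok = FALSE,
         n_obs = nrow(data), n_params = length(nm),
         spec = spec, design = design, data = data),
    class = "pk_fit"
  )
  if (compute_se) {
    se <- tryCatch(standard_errors(fit, data, spec, design),
                   error = function(e) NULL)
    if (!is.null(se)) {
      fit$covariance <- se$covariance
      fit$se <- se$se
      fit$rse_percent <- se$rse_percent
      fit$cov_ok <- se$cov_ok
    }
  }
  fit
}

# full central-difference Hessian with relative step `rel_step` per coordinate
.hessian_cd <- function(f, x, rel_step = 1e-4) {
  n <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  H <- matrix(NA_real_, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    ei <- replace(numeric(n), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(n), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

# covariance of the ML estimate from the ofv (= -2 logLik) Hessian
.cov_from_hessian <- function(H) {
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return(NULL) # not positive definite
  2 * solve(H)
}

#' Standard errors and relative standard errors of a fit
#'
#' Curvature-based uncertainty: the Hessian of the objective function
#' (-2 log-likelihood) is computed by central finite differences on the
#' estimation (log) scale, inverted to a covariance matrix, and transformed
#' to the reporting scale by the delta method. The relative standard error is
#' `RSE% = 100 * SE / |estimate|`. When the Hessian is not positive definite
#' the covariance step is flagged as failed and RSEs are withheld.
#'
#' @param fit a [fit_pk()] result.
#' @param data,spec,design the inputs of the fit; default to those stored in
#'   `fit`.
#' @return list with `covariance` (reporting scale), `se`, `rse_percent` and
#'   `cov_ok`.
#' @export
standard_errors <- function(fit, data = fit$data, spec = fit$spec,
                            design = fit$design) {
  stopifnot(inherits(fit, "pk_fit"))
  if (!fit$converged) stop("standard errors require a converged fit")
  nm <- names(fit$par)
  objective <- function(phi) {
    names(phi) <- nm
    neg2_loglik(.params_from_free(.from_est_scale(phi), spec), spec, data, design)
  }
  H <- .hessian_cd(objective, fit$est_par)
  cov_est <- .cov_from_hessian(H)
  if (is.null(cov_est)) {
    return(list(covariance = NULL, se = setNames(rep(NA_real_, length(nm)), nm),
                rse_percent = setNames(rep(NA_real_, length(nm)), nm),
                cov_ok = FALSE))
  }
  J <- diag(.jacobian_diag(fit$par), nrow = length(nm))
  cov_nat <- J %*% cov_est %*% J
  dimnames(cov_nat) <- list(nm, nm)
  se <- sqrt(pmax(diag(cov_nat), 0))
  rse <- 100 * se / abs(fit$par)
  list(covariance = cov_nat, se = setNames(se, nm),
       rse_percent = setNames(rse, nm), cov_ok = TRUE)
}

#' @export
print.pk_fit <- function(x, digits = 3, ...) {
  cat("Pharmacokinetic model fit (", x$n_obs, " observations, ",
      x$n_params, " parameters)\n", sep = "")
  cat("  OFV (-2 log-likelihood): ", format(x$ofv, digits = 8), "\n", sep = "")
  cat("  converged: ", x$converged,
      if (!x$cov_ok) "  [covariance step failed; RSEs withheld]", "\n", sep = "")
  stoch <- c("sigma2_prop", "sigma2_add")
  tab <- data.frame(
    Estimate = signif(x$par, digits),
    `RSE (%)` = if (x$cov_ok) round(x$rse_percent) else NA_integer_,
    check.names = FALSE
  )
  cat("\nStructural parameters\n")
  print(tab[!rownames(tab) %in% stoch, , drop = FALSE])
  if (any(rownames(tab) %in% stoch)) {
    cat("\nStochastic parameters\n")
    print(tab[rownames(tab) %in% stoch, , drop = FALSE])
  }
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) object$par

#' @export
logLik.pk_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}
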