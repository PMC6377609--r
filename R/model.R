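#' Pharmacokinetic parameter set
#'
#' Container for the structural, covariate and residual-error parameters of
#' the larval model. Which fields are used is decided by the accompanying
#' [model_spec()].
#'
#' @param ka_base zero-order absorption rate at the reference age (pmole/min).
#' @param ke_base first-order elimination rate constant at the reference age
#'   (1/min). Ignored under Michaelis-Menten elimination.
#' @param factor_a covariate coefficient on the absorption rate: the discrete
#'   fractional increase after the reference age (discrete form) or the slope
#'   per day (linear/power forms). Dimensionless, > -1.
#' @param slope_e covariate coefficient on the elimination rate constant,
#'   interpreted like `factor_a`. Dimensionless, > -1.
#' @param sigma2_prop variance of the proportional residual error
#'   (dimensionless).
#' @param sigma2_add variance of the additive residual error
#'   ((pmole/larva)^2).
#' @param vmax,km Michaelis-Menten maximal elimination rate (pmole/min) and
#'   Michaelis constant (pmole); only used when the model spec selects
#'   Michaelis-Menten elimination.
#' @param k12,k21 first-order exchange rate constants (1/min) with the
#'   peripheral compartment; only used by the two-compartment model.
#' @return an object of class `pk_parameters`.
#' @export
#' @examples
#' pk_parameters(ka_base = 0.289, ke_base = 0.0193,
#'               factor_a = 1.06, slope_e = 0.175,
#'               sigma2_prop = 0.109, sigma2_add = 0.00844)
pk_parameters <- function(ka_base, ke_base,
                          factor_a = 0, slope_e = 0,
                          sigma2_prop = 0, sigma2_add = 0,
                          vmax = NA_real_, km = NA_real_,
                          k12 = NA_real_, k21 = NA_real_) {
  p <- list(ka_base = ka_base, ke_base = ke_base,
            factor_a = factor_a, slope_e = slope_e,
            sigma2_prop = sigma2_prop, sigma2_add = sigma2_add,
            vmax = vmax, km = km, k12 = k12, k21 = k21)
  for (nm in c("ka_base", "ke_base", "sigma2_prop", "sigma2_add")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a single non-negative finite number")
  }
  for (nm in c("factor_a", "slope_e")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= -1)
      stop("'", nm, "' must be a single finite number greater than -1")
  }
  for (nm in c("vmax", "km", "k12", "k21")) {
    v <- p[[nm]]
    if (!is.na(v) && (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0))
      stop("'", nm, "' must be non-negative when supplied")
  }
  if (!is.na(p$km) && p$km <= 0) stop("'km' must be strictly positive")
  structure(p, class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("PK parameters\n")
  v <- unlist(x)
  v <- v[!is.na(v)]
  for (nm in names(v)) cat(sprintf("  %-12s %g\n", nm, v[[nm]]))
  invisible(x)
}

#' Structural, covariate and error model specification
#'
#' Selects one candidate among the model variants considered for the larval
#' data: one or two compartments; first-order or Michaelis-Menten (saturable)
#' elimination; a covariate functional form on the absorption and elimination
#' rate constants; and an additive, proportional or combined residual-error
#' model. For the two-compartment variant the sum of the amounts in both
#' compartments is fitted to the observed totals, and elimination takes place
#' from the central compartment only.
#'
#' @param n_compartments 1 or 2.
#' @param elimination `"first_order"` or `"michaelis_menten"`.
#' @param ka_covariate,ke_covariate covariate form on the absorption /
#'   elimination rate: `"none"`, `"linear"`, `"power"` or `"discrete"`. Under
#'   Michaelis-Menten elimination `ke_covariate` must be `"none"`.
#' @param error_model `"additive"`, `"proportional"` or `"combined"`.
#' @param reference_age reference age in dpf for the covariate functions.
#' @return an object of class `model_spec`.
#' @export
#' @examples
#' # the final larval paracetamol model
#' model_spec(ka_covariate = "discrete", ke_covariate = "power",
#'            error_model = "combined")
model_spec <- function(n_compartments = 1L,
                       elimination = c("first_order", "michaelis_menten"),
                       ka_covariate = c("none", "linear", "power", "discrete"),
                       ke_covariate = c("none", "linear", "power", "discrete"),
                       error_model = c("combined", "additive", "proportional"),
                       reference_age = 3) {
  elimination <- match.arg(elimination)
  ka_covariate <- match.arg(ka_covariate)
  ke_covariate <- match.arg(ke_covariate)
  error_model <- match.arg(error_model)
  if (!n_compartments %in% c(1L, 2L)) stop("'n_compartments' must be 1 or 2")
  if (elimination == "michaelis_menten" && ke_covariate != "none")
    stop("covariates on the elimination rate are only supported for first-order elimination")
  structure(
    list(n_compartments = as.integer(n_compartments),
         elimination = elimination,
         ka_covariate = ka_covariate,
         ke_covariate = ke_covariate,
         error_model = error_model,
         reference_age = reference_age),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("PK model specification\n")
  cat("  compartments:", x$n_compartments, "| elimination:", x$elimination, "\n")
  cat("  ka covariate:", x$ka_covariate, "| ke covariate:", x$ke_covariate,
      "(ref", x$reference_age, "dpf)\n")
  cat("  residual error:", x$error_model, "\n")
  invisible(x)
}

# resolve age-dependent absorption / elimination rates through the covariate
# machinery so predictions and the standalone covariate_value() agree by
# construction
.ka_at <- function(params, spec, age) {
  covariate_value(
    covariate_spec(spec$ka_covariate, params$ka_base, params$factor_a,
                   spec$reference_age),
    age
  )
}

.ke_at <- function(params, spec, age) {
  covariate_value(
    covariate_spec(spec$ke_covariate, params$ke_base, params$slope_e,
                   spec$reference_age),
    age
  )
}

# closed-form 1-compartment, first-order solution; vectorised over t
.closed_form_1c <- function(ka, ke, t, arm, t_d) {
  if (ke <= 0) { # limiting case: pure zero-order accumulation
    up <- ka * t
    down <- ka * t_d
  } else {
    a_ss <- ka / ke
    up <- a_ss * (1 - exp(-ke * t))
    down <- a_ss * (1 - exp(-ke * t_d)) * exp(-ke * (t - t_d))
  }
  if (arm == "constant") up else ifelse(t <= t_d, up, down)
}

# numerical solution for any variant; returns amounts at `times` (sorted not
# required). Absorption switches off at t_d for the washout arm; integration
# is split at the switch so the solver never steps across the discontinuity.
.ode_amounts <- function(params, spec, age, arm, times, design,
                         rtol = 1e-8, atol = 1e-10) {
  ka <- .ka_at(params, spec, age)
  two_cpt <- spec$n_compartments == 2L
  mm <- spec$elimination == "michaelis_menten"
  if (mm && (is.na(params$vmax) || is.na(params$km)))
    stop("Michaelis-Menten elimination requires 'vmax' and 'km'")
  if (two_cpt && (is.na(params$k12) || is.na(params$k21)))
    stop("the two-compartment model requires 'k12' and 'k21'")
  ke <- if (mm) NA_real_ else .ke_at(params, spec, age)

  deriv <- function(t, y, parms) {
    elim <- if (mm) params$vmax * y[1] / (params$km + y[1]) else ke * y[1]
    input <- if (parms$on) ka else 0
    if (two_cpt) {
      d1 <- input - elim - params$k12 * y[1] + params$k21 * y[2]
      d2 <- params$k12 * y[1] - params$k21 * y[2]
      list(c(d1, d2))
    } else {
      list(input - elim)
    }
  }

  y0 <- if (two_cpt) c(0, 0) else 0
  t_d <- design$treatment_duration_min
  solve_piece <- function(y0, tt, on) {
    out <- tryCatch(
      deSolve::ode(y = y0, times = tt, func = deriv, parms = list(on = on),
                   method = "lsoda", rtol = rtol, atol = atol),
      warning = function(w) stop("ODE integration failed: ", conditionMessage(w)),
      error = function(e) stop("ODE integration failed: ", conditionMessage(e))
    )
    out
  }

  ord <- order(times)
  ts <- times[ord]
  if (arm == "constant" || max(ts) <= t_d) {
    tt <- unique(c(0, ts))
    out <- solve_piece(y0, tt, on = TRUE)
    amounts <- .ode_lookup(out, ts, two_cpt)
  } else {
    pre <- ts[ts <= t_d]
    post <- ts[ts > t_d]
    tt1 <- unique(c(0, pre, t_d))
    out1 <- solve_piece(y0, tt1, on = TRUE)
    y_td <- out1[nrow(out1), -1]
    tt2 <- unique(c(t_d, post))
    out2 <- solve_piece(as.numeric(y_td), tt2, on = FALSE)
    amounts <- c(
      if (length(pre)) .ode_lookup(out1, pre, two_cpt) else numeric(0),
      .ode_lookup(out2, post, two_cpt)
    )
  }
  amounts[order(ord)]
}

.ode_lookup <- function(out, ts, two_cpt) {
  idx <- match(ts, out[, 1])
  if (anyNA(idx)) stop("internal error: ODE output missing requested times")
  if (two_cpt) out[idx, 2] + out[idx, 3] else out[idx, 2]
}

#' Predict the internal amount per larva
#'
#' Model-predicted total amount of compound in one larva at given times, ages
#' and experimental arms. The linear one-compartment model uses the closed
#' form: under constant treatment `A(t) = ka/ke * (1 - exp(-ke t))`, and in
#' the washout arm `A(t) = A(T_d) * exp(-ke (t - T_d))` for `t >= T_d`, where
#' `T_d` is the treatment duration from the design. Two-compartment and
#' Michaelis-Menten variants are integrated numerically with an adaptive
#' stiff-capable solver; the two-compartment prediction is the sum of the
#' amounts in both compartments. Absorption and elimination rates are first
#' resolved through the covariate forms in `spec`.
#'
#' @param params a [pk_parameters()].
#' @param spec a [model_spec()].
#' @param age age(s) in dpf.
#' @param arm `"constant"` or `"washout"`; recycled against `age`/`time`.
#' @param time time(s) since treatment start (min), non-negative.
#' @param design a [design_spec()]; supplies the washout switch time.
#' @param method `"auto"` (closed form where exact, otherwise ODE),
#'   `"closed_form"` (linear one-compartment only) or `"ode"`.
#' @return numeric vector of predicted amounts (pmole/larva).
#' @export
#' @examples
#' p <- pk_parameters(ka_base = 0.289, ke_base = 0.0193)
#' m <- model_spec()
#' d <- default_study_design()
#' predict_amount(p, m, age = 3, arm = "constant", time = c(0, 60, 180), design = d)
predict_amount <- function(params, spec, age, arm, time, design,
                           method = c("auto", "closed_form", "ode")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "pk_parameters"), inherits(spec, "model_spec"),
            inherits(design, "design_spec"))
  if (any(time < 0)) stop("'time' must be non-negative")
  arm <- as.character(arm)
  if (!all(arm %in% c("constant", "washout")))
    stop("'arm' must be \"constant\" or \"washout\"")
  n <- max(length(age), length(arm), length(time))
  age <- rep_len(age, n); arm <- rep_len(arm, n); time <- rep_len(time, n)

  linear_1c <- spec$n_compartments == 1L && spec$elimination == "first_order"
  if (method == "closed_form" && !linear_1c)
    stop("the closed form is only available for the linear one-compartment model")
  use_closed <- method == "closed_form" || (method == "auto" && linear_1c)

  out <- numeric(n)
  for (grp in split(seq_len(n), list(age, arm), drop = TRUE)) {
    a <- age[grp[1]]; ar <- arm[grp[1]]
    if (use_closed) {
      out[grp] <- .closed_form_1c(.ka_at(params, spec, a), .ke_at(params, spec, a),
                                  time[grp], ar, design$treatment_duration_min)
    } else {
      out[grp] <- .ode_amounts(params, spec, a, ar, time[grp], design)
    }
  }
  out
}

# predictions for the rows of an observation table (internal fast path)
.predict_obs <- function(params, spec, data, design, method = "auto") {
  predict_amount(params, spec, data$age_dpf, data$arm, data$time_min, design,
                 method = method)
}

#' Time to reach a fraction of steady state
#'
#' Under constant treatment the linear one-compartment amount approaches the
#' plateau `ka/ke`; the time to reach a fraction `f` of that plateau is
#' `-ln(1 - f)/ke`, independent of the absorption rate.
#'
#' @param ke first-order elimination rate constant (1/min), > 0.
#' @param fraction target fraction of steady state, strictly between 0 and 1.
#' @return time in minutes.
#' @export
#' @examples
#' time_to_steady_state(ke = 0.0193, fraction = 0.9)
time_to_steady_state <- function(ke, fraction = 0.9) {
  stopifnot(is.numeric(ke), all(ke > 0))
  if (!is.numeric(fraction) || any(fraction <= 0) || any(fraction >= 1))
    stop("'fraction' must lie strictly between 0 and 1")
  -log(1 - fraction) / ke
}

#' Clearance from the elimination rate constant and larval volume
#'
#' Absolute clearance obtained by multiplying the first-order elimination
#' rate constant by the total larval volume, assuming the distribution volume
#' equals the total volume of the larva with homogeneous distribution. The
#' factor 60 converts from per-minute to per-hour.
#'
#' @param ke elimination rate constant (1/min), >= 0.
#' @param total_volume_nl total larval volume (nL), > 0.
#' @return clearance in nL/h.
#' @export
#' @examples
#' clearance(ke = 0.0193, total_volume_nl = 253) # 3 dpf larva
clearance <- function(ke, total_volume_nl) {
  stopifnot(is.numeric(ke), all(ke >= 0))
  if (!is.numeric(total_volume_nl) || any(total_volume_nl <= 0))
    stop("'total_volume_nl' must be strictly positive")
  ke * total_volume_nl * 60
}
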