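#' Larval bodyweight from total volume
#'
#' Converts a total larval volume to bodyweight assuming a tissue density of
#' 0.997 g/mL: `grams = volume_nL * 1e-6 mL/nL * density`.
#'
#' @param volume_nl total larval volume (nL), > 0.
#' @param density_g_per_ml tissue density (g/mL), default 0.997.
#' @return bodyweight in grams.
#' @export
#' @examples
#' bodyweight_from_volume(253) # 3 dpf larva
bodyweight_from_volume <- function(volume_nl, density_g_per_ml = 0.997) {
  if (!is.numeric(volume_nl) || any(volume_nl <= 0))
    stop("'volume_nl' must be strictly positive")
  stopifnot(is.numeric(density_g_per_ml), all(density_g_per_ml > 0))
  volume_nl * 1e-6 * density_g_per_ml
}

# multiplicative factor that brings a clearance in `unit` to nL/h
.cl_unit_to_nl_per_h <- c(
  "nL/h" = 1, "uL/h" = 1e3, "mL/h" = 1e6, "L/h" = 1e9,
  "nL/min" = 60, "uL/min" = 60e3, "mL/min" = 60e6, "L/min" = 60e9
)

#' Interspecies allometric regression of clearance on bodyweight
#'
#' Ordinary least squares of `log10(clearance)` on `log10(bodyweight)`,
#' fitted on mature individuals only; immature records are retained in the
#' returned object for comparison/plotting but never enter the regression.
#' The 95% confidence band is the mean-prediction (confidence) t-interval of
#' the regression line.
#'
#' @param records data frame with columns `species`, `bodyweight_g`,
#'   `clearance`, `mature` (logical), and optionally `clearance_unit` (one of
#'   `"nL/h"`, `"uL/h"`, `"mL/h"`, `"L/h"`, `"nL/min"`, `"uL/min"`,
#'   `"mL/min"`, `"L/min"`; default `"nL/h"`). All clearances are harmonised
#'   to nL/h before fitting.
#' @param conf_level confidence level of the band (default 0.95).
#' @return object of class `allometric_fit` with elements `lm` (the fitted
#'   model on log10 scales), `records` (harmonised), `slope`, `intercept`,
#'   `sigma2` (residual variance) and `conf_level`.
#' @seealso [predict.allometric_fit()], [fraction_of_lower_bound()]
#' @export
fit_allometric <- function(records, conf_level = 0.95) {
  needed <- c("species", "bodyweight_g", "clearance", "mature")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("species table is missing columns: ", paste(missing, collapse = ", "))
  if (any(records$bodyweight_g <= 0) || any(records$clearance <= 0))
    stop("bodyweights and clearances must be strictly positive")
  if ("clearance_unit" %in% names(records)) {
    fac <- .cl_unit_to_nl_per_h[records$clearance_unit]
    if (anyNA(fac))
      stop("unknown clearance unit(s): ",
           paste(unique(records$clearance_unit[is.na(fac)]), collapse = ", "))
    records$clearance_nl_per_h <- records$clearance * fac
  } else {
    records$clearance_nl_per_h <- records$clearance
  }
  mature <- records[isTRUE_vec(records$mature), , drop = FALSE]
  if (nrow(mature) < 3L)
    stop("allometric regression needs at least 3 mature species records")
  if (length(unique(mature$bodyweight_g)) < 2L)
    stop("mature records must span distinct bodyweights")
  dat <- data.frame(log_bw = log10(mature$bodyweight_g),
                    log_cl = log10(mature$clearance_nl_per_h))
  fit <- lm(log_cl ~ log_bw, data = dat)
  structure(
    list(lm = fit, records = records,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         sigma2 = summary(fit)$sigma^2, conf_level = conf_level),
    class = "allometric_fit"
  )
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Predicted clearance with confidence band at given bodyweights
#'
#' Evaluates the allometric regression line and its mean-prediction
#' confidence band at new bodyweights, back-transformed to the clearance
#' scale (nL/h). Bodyweights outside the range of the mature records used in
#' the fit are flagged as extrapolated — extrapolation below the fitted range
#' is exactly how larval clearance is placed against the mature-species line.
#'
#' @param object an [fit_allometric()] result.
#' @param bodyweight_g bodyweight(s) in grams.
#' @param ... unused.
#' @return data frame with columns `bodyweight_g`, `fit`, `lwr`, `upr`
#'   (clearances, nL/h) and `extrapolated`.
#' @export
predict.allometric_fit <- function(object, bodyweight_g, ...) {
  stopifnot(is.numeric(bodyweight_g), all(bodyweight_g > 0))
  nd <- data.frame(log_bw = log10(bodyweight_g))
  band <- predict(object$lm, newdata = nd, interval = "confidence",
                  level = object$conf_level)
  rng <- range(object$lm$model$log_bw)
  data.frame(
    bodyweight_g = bodyweight_g,
    fit = 10^band[, "fit"],
    lwr = 10^band[, "lwr"],
    upr = 10^band[, "upr"],
    extrapolated = nd$log_bw < rng[1] | nd$log_bw > rng[2]
  )
}

#' Larval clearance as a fraction of the extrapolated lower confidence bound
#'
#' Expresses a larval clearance as a percentage of the lower bound of the
#' confidence band of the mature-species allometric regression, extrapolated
#' to the larval bodyweight: `100 * CL_larva / CL_lower(BW_larva)`.
#'
#' @param larval_cl larval clearance in nL/h.
#' @param larval_bw_g larval bodyweight in grams.
#' @param fit an [fit_allometric()] result.
#' @return percentage (vectorised over larvae); attribute `extrapolated`
#'   flags bodyweights outside the fitted range.
#' @export
fraction_of_lower_bound <- function(larval_cl, larval_bw_g, fit) {
  stopifnot(inherits(fit, "allometric_fit"),
            is.numeric(larval_cl), all(larval_cl > 0))
  band <- predict(fit, bodyweight_g = larval_bw_g)
  out <- 100 * larval_cl / band$lwr
  attr(out, "extrapolated") <- band$extrapolated
  out
}

#' @export
print.allometric_fit <- function(x, ...) {
  n_mat <- sum(isTRUE_vec(x$records$mature))
  cat("Allometric regression of log10 clearance on log10 bodyweight\n")
  cat("  fitted on ", n_mat, " mature species records (",
      nrow(x$records) - n_mat, " immature retained for comparison)\n", sep = "")
  cat(sprintf("  log10(CL) = %.4f + %.4f * log10(BW)   [CL nL/h, BW g]\n",
              x$intercept, x$slope))
  cat(sprintf("  residual SD (log10): %.4f | %d%% confidence band\n",
              sqrt(x$sigma2), round(100 * x$conf_level)))
  invisible(x)
}
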