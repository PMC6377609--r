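#' Weighted residuals (CWRES-equivalent) for a fitted model
#'
#' Per-observation goodness-of-fit quantities: prediction, residual, the
#' residual-error variance implied by the fitted error model, and the
#' weighted residual `(obs - pred) / sqrt(variance)`. With no between-larva
#' random effects in the model, conditional weighted residuals reduce exactly
#' to this variance-weighted form; for a correctly specified model they
#' should scatter around zero with unit variance and show no trend against
#' time or predictions.
#'
#' @param fit a converged [fit_pk()] result.
#' @param data,spec,design inputs of the fit; default to those stored in
#'   `fit`.
#' @return data frame of class `gof_records`: one row per observation with
#'   columns `sample_id`, `age_dpf`, `arm`, `time_min`, `observed`,
#'   `predicted`, `residual`, `variance`, `wres`.
#' @export
weighted_residuals <- function(fit, data = fit$data, spec = fit$spec,
                               design = fit$design) {
  stopifnot(inherits(fit, "pk_fit"))
  if (!fit$converged) stop("weighted residuals require a converged fit")
  data <- validate_pk_data(data)
  pred <- .predict_obs(fit$estimates, spec, data, design)
  v <- .obs_variance(pred, spec$error_model,
                     fit$estimates$sigma2_prop, fit$estimates$sigma2_add)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("zero or non-finite residual variance; cannot weight residuals")
  res <- data$amount_pmole - pred
  out <- data.frame(
    sample_id = data$sample_id,
    age_dpf = data$age_dpf,
    arm = data$arm,
    time_min = data$time_min,
    observed = data$amount_pmole,
    predicted = pred,
    residual = res,
    variance = v,
    wres = res / sqrt(v),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gof_records", "data.frame")
  out
}

#' Export goodness-of-fit tables (and optional plots)
#'
#' Writes the observed-versus-predicted / weighted-residual table produced by
#' [weighted_residuals()] as delimited text, and optionally renders the three
#' standard diagnostic panels (observed vs predicted, weighted residuals vs
#' time, weighted residuals vs predicted) to a PDF. The tables are the
#' primary artifact; the plot is a thin layer over them.
#'
#' @param records a `gof_records` table from [weighted_residuals()].
#' @param path output CSV path, or `NULL` to skip writing.
#' @param plot_path optional PDF path for the diagnostic panels.
#' @return the records, invisibly.
#' @export
gof_table <- function(records, path = NULL, plot_path = NULL) {
  if (!inherits(records, "data.frame") || nrow(records) == 0L)
    stop("'records' must be a non-empty goodness-of-fit table")
  needed <- c("observed", "predicted", "residual", "variance", "wres")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  if (!is.null(path))
    write.csv(records, path, row.names = FALSE, quote = FALSE)
  if (!is.null(plot_path)) {
    grDevices::pdf(plot_path, width = 9, height = 3.2)
    on.exit(grDevices::dev.off())
    op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op), add = TRUE, after = FALSE)
    lim <- range(records$observed, records$predicted)
    plot(records$predicted, records$observed, xlim = lim, ylim = lim,
         xlab = "predicted amount (pmole)", ylab = "observed amount (pmole)",
         main = "Observed vs predicted")
    graphics::abline(0, 1, lty = 2)
    plot(records$time_min, records$wres,
         xlab = "time (min)", ylab = "weighted residual",
         main = "WRES vs time")
    graphics::abline(h = 0, lty = 2)
    plot(records$predicted, records$wres,
         xlab = "predicted amount (pmole)", ylab = "weighted residual",
         main = "WRES vs predicted")
    graphics::abline(h = 0, lty = 2)
  }
  invisible(records)
}
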