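#' Experimental design of a waterborne-treatment study
#'
#' Declares the sampling design: larval ages, sampling times for the constant
#' waterborne-treatment arm and for the washout arm, the treatment duration
#' preceding washout, replicates per time point and the number of pooled
#' larvae per sample.
#'
#' In the washout arm larvae are exposed for `treatment_duration_min` minutes
#' and then transferred to drug-free medium; washout sampling times are
#' measured from treatment start, so they must be at or after
#' `treatment_duration_min` and at or before `washout_end_min`.
#'
#' @param ages integer ages in dpf.
#' @param treatment_times sampling times (min) for the constant-treatment arm,
#'   within `treatment_window`.
#' @param washout_times sampling times (min) for the washout arm.
#' @param treatment_duration_min exposure length before washout (min).
#' @param washout_end_min last admissible washout sampling time (min).
#' @param treatment_window admissible `[min, max]` window for constant-arm
#'   sampling times (min).
#' @param replicates replicate samples per (age, arm, time) point; at least 3.
#' @param pool_size larvae pooled into one sample.
#' @return an object of class `design_spec`.
#' @seealso [default_study_design()]
#' @export
design_spec <- function(ages = c(3L, 4L, 5L),
                        treatment_times,
                        washout_times,
                        treatment_duration_min = 60,
                        washout_end_min = 240,
                        treatment_window = c(0, 180),
                        replicates = 3L,
                        pool_size = 5L) {
  stopifnot(length(ages) >= 1L, all(ages == as.integer(ages)))
  stopifnot(is.numeric(treatment_times), all(is.finite(treatment_times)))
  stopifnot(is.numeric(washout_times), all(is.finite(washout_times)))
  stopifnot(treatment_duration_min > 0, washout_end_min > treatment_duration_min)
  if (any(treatment_times < treatment_window[1] | treatment_times > treatment_window[2]))
    stop("constant-treatment sampling times must lie within [",
         treatment_window[1], ", ", treatment_window[2], "] min")
  if (any(washout_times < treatment_duration_min | washout_times > washout_end_min))
    stop("washout sampling times must lie within [",
         treatment_duration_min, ", ", washout_end_min, "] min")
  if (replicates < 3L)
    stop("the design requires at least triplicate measurements per time point")
  stopifnot(pool_size >= 1L)
  structure(
    list(ages = as.integer(ages),
         treatment_times = sort(treatment_times),
         washout_times = sort(washout_times),
         treatment_duration_min = treatment_duration_min,
         washout_end_min = washout_end_min,
         treatment_window = treatment_window,
         replicates = as.integer(replicates),
         pool_size = as.integer(pool_size)),
    class = "design_spec"
  )
}

#' Default study design for the larval paracetamol experiment
#'
#' The design the analysis was developed on: larvae of 3, 4 and 5 dpf; a
#' constant 1 mM waterborne-treatment arm sampled over 0--180 min; a washout
#' arm treated for 60 min and sampled until 240 min; pooled samples of 5
#' larvae; triplicate measurements at every time point. Sampling grids are a
#' reconstruction of those windows with 8 points per arm.
#'
#' @param replicates replicates per time point (default 3).
#' @return a [design_spec()].
#' @export
#' @examples
#' default_study_design()
default_study_design <- function(replicates = 3L) {
  design_spec(
    ages = c(3L, 4L, 5L),
    treatment_times = c(10, 20, 30, 60, 90, 120, 150, 180),
    washout_times = c(70, 80, 90, 120, 150, 180, 210, 240),
    treatment_duration_min = 60,
    washout_end_min = 240,
    treatment_window = c(0, 180),
    replicates = replicates,
    pool_size = 5L
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Waterborne-treatment study design\n")
  cat("  ages:", paste(x$ages, collapse = ", "), "dpf\n")
  cat("  constant treatment sampled at:", paste(x$treatment_times, collapse = ", "), "min\n")
  cat("  washout (treatment ", x$treatment_duration_min, " min) sampled at: ",
      paste(x$washout_times, collapse = ", "), " min\n", sep = "")
  cat("  replicates per point:", x$replicates,
      "| pooled larvae per sample:", x$pool_size, "\n")
  invisible(x)
}
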