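# ---- dataset format --------------------------------------------------------
#
# One row per pooled-larvae sample, comma-delimited with dot decimals:
#   sample_id, age_dpf, arm, time_min, amount_pmole, pool_size
# arm is "constant" or "washout"; times are minutes since treatment start.

.pk_columns <- c("sample_id", "age_dpf", "arm", "time_min", "amount_pmole",
                 "pool_size")

#' Validate an observation table
#'
#' Checks the column set, types and invariants of a pooled-sample observation
#' table: arms restricted to `constant`/`washout`, non-negative finite times
#' and amounts, positive integer pool sizes. When a design is supplied,
#' washout times are additionally required to be at or after the treatment
#' duration. Errors name the offending row and column.
#'
#' @param data data frame to validate.
#' @param design optional [design_spec()] for design-dependent checks.
#' @return the validated data frame (with `arm` as character), invisibly
#'   usable downstream.
#' @export
validate_pk_data <- function(data, design = NULL) {
  if (!is.data.frame(data)) stop("dataset must be a data frame")
  if (nrow(data) == 0L) stop("dataset is empty: no observation rows")
  missing <- setdiff(setdiff(.pk_columns, "sample_id"), names(data))
  if (length(missing))
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "))
  if (!"sample_id" %in% names(data))
    data$sample_id <- sprintf("obs_%04d", seq_len(nrow(data)))
  data$arm <- as.character(data$arm)
  bad <- which(!data$arm %in% c("constant", "washout"))
  if (length(bad))
    stop("row ", bad[1], ", column 'arm': unknown arm \"", data$arm[bad[1]],
         "\" (expected \"constant\" or \"washout\")")
  .check_num <- function(col, min = 0) {
    v <- suppressWarnings(as.numeric(data[[col]]))
    bad <- which(!is.finite(v) | v < min)
    if (length(bad))
      stop("row ", bad[1], ", column '", col, "': value \"",
           data[[col]][bad[1]], "\" is not a finite number >= ", min)
    v
  }
  data$age_dpf <- as.integer(.check_num("age_dpf"))
  data$time_min <- .check_num("time_min")
  data$amount_pmole <- .check_num("amount_pmole")
  data$pool_size <- as.integer(.check_num("pool_size", min = 1))
  if (!is.null(design)) {
    bad <- which(data$arm == "washout" &
                 data$time_min < design$treatment_duration_min)
    if (length(bad))
      stop("row ", bad[1], ", column 'time_min': washout observation at ",
           data$time_min[bad[1]], " min precedes the treatment duration of ",
           design$treatment_duration_min, " min")
  }
  data
}

#' Read a pooled-sample observation dataset
#'
#' Reads and validates the delimited observation format (header
#' `sample_id,age_dpf,arm,time_min,amount_pmole,pool_size`).
#'
#' @param path CSV file path.
#' @return validated observation data frame.
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  validate_pk_data(raw)
}

#' Write a pooled-sample observation dataset
#'
#' @param data observation data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(data, path) {
  data <- validate_pk_data(data)
  write.csv(data[, .pk_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an interspecies clearance table
#'
#' Delimited text with header `species,bodyweight_g,clearance,clearance_unit,
#' mature`. The `clearance_unit` column declares the units the table is
#' expressed in (see [fit_allometric()] for the supported units); `mature` is
#' logical.
#'
#' @param path CSV file path.
#' @return data frame ready for [fit_allometric()].
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("species table not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("species", "bodyweight_g", "clearance", "mature")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("species table is missing column(s): ", paste(missing, collapse = ", "))
  tab$mature <- as.logical(tab$mature)
  tab
}

# ---- declarative simulation config ----------------------------------------

#' Read a simulation configuration from YAML
#'
#' Declarative counterpart of [simulation_config()]: keys `seed`, `design`
#' (fields of [design_spec()]), `truth` (fields of [pk_parameters()]) and
#' `model` (fields of [model_spec()]). Omitted design fields default to the
#' study design of [default_study_design()]; omitted model fields to the
#' final larval model (discrete absorption covariate, power elimination
#' covariate, combined error).
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's `seed` key.
#' @return a [simulation_config()].
#' @export
read_sim_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$truth)) stop("config must supply a 'truth' block")
  dd <- default_study_design()
  design_args <- modifyList(
    list(ages = dd$ages, treatment_times = dd$treatment_times,
         washout_times = dd$washout_times,
         treatment_duration_min = dd$treatment_duration_min,
         washout_end_min = dd$washout_end_min,
         replicates = dd$replicates, pool_size = dd$pool_size),
    if (is.null(cfg$design)) list() else cfg$design
  )
  design <- do.call(design_spec, design_args)
  spec_args <- modifyList(
    list(ka_covariate = "discrete", ke_covariate = "power",
         error_model = "combined"),
    if (is.null(cfg$model)) list() else cfg$model
  )
  spec <- do.call(model_spec, spec_args)
  truth <- do.call(pk_parameters, cfg$truth)
  seed <- if (!is.null(seed)) seed
          else if (!is.null(cfg$seed)) cfg$seed
          else stop("no seed supplied (config 'seed' key or argument)")
  simulation_config(design, truth, spec, seed)
}

# ---- fit report ------------------------------------------------------------

#' Write a fit report (plain text and machine-readable)
#'
#' Emits two artifacts for a fitted model: `<prefix>.txt`, a human-readable
#' table of estimates and relative standard errors split into structural and
#' stochastic parameters, and `<prefix>.json`, the same content as
#' key/value pairs plus the objective function value and convergence
#' metadata.
#'
#' @param fit a [fit_pk()] result.
#' @param prefix output path prefix.
#' @return character vector of the two paths written, invisibly.
#' @export
write_fit_report <- function(fit, prefix) {
  stopifnot(inherits(fit, "pk_fit"))
  txt <- paste0(prefix, ".txt")
  con <- file(txt, "w")
  sink(con)
  print(fit)
  sink()
  close(con)
  js <- paste0(prefix, ".json")
  payload <- list(
    model = fit$spec[c("n_compartments", "elimination", "ka_covariate",
                       "ke_covariate", "error_model", "reference_age")],
    estimates = as.list(fit$par),
    rse_percent = if (fit$cov_ok) as.list(fit$rse_percent) else NULL,
    ofv = fit$ofv,
    converged = fit$converged,
    covariance_step_ok = fit$cov_ok,
    n_obs = fit$n_obs,
    n_params = fit$n_params
  )
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(txt, js))
}
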