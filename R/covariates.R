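#' Covariate function on a pharmacokinetic parameter
#'
#' Describes how a structural parameter changes with larval age (days post
#' fertilisation, dpf). Three functional families are supported in addition to
#' `"none"`:
#' \describe{
#'   \item{linear}{`P = P_base * (1 + slope * (age - ref))`}
#'   \item{power}{`P = P_base * (1 + slope)^(age - ref)`}
#'   \item{discrete}{a separate multiplicative factor per age level,
#'     `P = P_base * (1 + factor_age)`, with factor 0 at the reference age}
#' }
#'
#' @param form one of `"none"`, `"linear"`, `"power"`, `"discrete"`.
#' @param base_value parameter value at the reference age (must be finite).
#' @param slope_or_factor for `"linear"`/`"power"`, the fractional change per
#'   day; for `"discrete"`, either a single factor applied to every non-reference
#'   age or a named numeric vector with one factor per age level (names are
#'   ages in dpf). Ignored for `"none"`.
#' @param reference_age reference age in dpf (default 3, the youngest
#'   post-hatching age studied).
#'
#' @return an object of class `covariate_spec`.
#' @seealso [covariate_value()]
#' @export
#' @examples
#' # elimination rate increasing 17.5% per day of development
#' ke_cov <- covariate_spec("power", base_value = 0.0193, slope_or_factor = 0.175)
#' covariate_value(ke_cov, age = 5)
covariate_spec <- function(form = c("none", "linear", "power", "discrete"),
                           base_value,
                           slope_or_factor = 0,
                           reference_age = 3) {
  form <- match.arg(form)
  stopifnot(is.numeric(base_value), length(base_value) == 1L, is.finite(base_value))
  stopifnot(is.numeric(reference_age), length(reference_age) == 1L)
  if (form != "none") {
    stopifnot(is.numeric(slope_or_factor), length(slope_or_factor) >= 1L,
              all(is.finite(slope_or_factor)))
    if (form != "discrete" && length(slope_or_factor) != 1L)
      stop("'slope_or_factor' must be a single slope for the ", form, " form")
  }
  structure(
    list(form = form, base_value = base_value,
         slope_or_factor = slope_or_factor, reference_age = reference_age),
    class = "covariate_spec"
  )
}

#' Evaluate a covariate function at a given age
#'
#' Resolves the parameter value at one or more larval ages according to the
#' functional form held in a [covariate_spec()].
#'
#' @param spec a [covariate_spec()].
#' @param age integer age(s) in dpf.
#' @return numeric vector of parameter values, one per age.
#' @export
#' @examples
#' covariate_value(covariate_spec("power", 0.0193, 0.175), age = c(3, 4, 5))
covariate_value <- function(spec, age) {
  stopifnot(inherits(spec, "covariate_spec"), is.numeric(age), all(is.finite(age)))
  d <- age - spec$reference_age
  switch(spec$form,
    none = rep(spec$base_value, length(age)),
    linear = spec$base_value * (1 + spec$slope_or_factor * d),
    power = spec$base_value * (1 + spec$slope_or_factor)^d,
    discrete = {
      f <- spec$slope_or_factor
      fac <- if (is.null(names(f)) && length(f) == 1L) {
        # single factor: applies to every age other than the reference
        ifelse(d == 0, 0, f)
      } else {
        if (is.null(names(f)))
          stop("discrete covariate with multiple factors requires names (ages in dpf)")
        out <- numeric(length(age))
        for (i in seq_along(age)) {
          if (d[i] == 0) {
            out[i] <- 0
          } else {
            key <- as.character(age[i])
            if (!key %in% names(f))
              stop("no discrete covariate factor supplied for age level ",
                   age[i], " dpf")
            out[i] <- f[[key]]
          }
        }
        out
      }
      spec$base_value * (1 + fac)
    }
  )
}

#' @export
print.covariate_spec <- function(x, ...) {
  cat("Covariate function (", x$form, ")\n", sep = "")
  cat("  base value at ", x$reference_age, " dpf: ", format(x$base_value), "\n", sep = "")
  if (x$form %in% c("linear", "power"))
    cat("  slope: ", format(x$slope_or_factor), " per day\n", sep = "")
  if (x$form == "discrete")
    cat("  factor(s): ", paste(format(x$slope_or_factor), collapse = ", "), "\n", sep = "")
  invisible(x)
}
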