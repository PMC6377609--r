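# synthetic interspecies table: clearance scaling allometrically with
# bodyweight across mature vertebrates (1 g .. 100 kg), log10 scatter `sigma`
make_species <- function(n = 10, intercept = 6.6, slope = 0.75, sigma = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  log_bw <- seq(0, 5, length.out = n)
  log_cl <- intercept + slope * log_bw + rnorm(n, 0, sigma)
  data.frame(species = paste0("sp", seq_len(n)),
             bodyweight_g = 10^log_bw,
             clearance = 10^log_cl,
             clearance_unit = "nL/h",
             mature = TRUE,
             stringsAsFactors = FALSE)
}

test_that("bodyweight follows from volume and density", {
  expect_equal(bodyweight_from_volume(253), 253e-6 * 0.997)
  expect_equal(bodyweight_from_volume(300), 2.991e-4, tolerance = 1e-6)
  expect_equal(bodyweight_from_volume(1e6, density_g_per_ml = 1), 1)
  expect_error(bodyweight_from_volume(0), "positive")
})

test_that("records on an exact line are recovered exactly, immature points never fit", {
  tab <- make_species(8, intercept = 6.6, slope = 0.75, sigma = 0)
  # an exactly collinear fixture makes summary.lm grumble about perfect fits
  fit <- suppressWarnings(fit_allometric(tab))
  expect_equal(fit$slope, 0.75, tolerance = 1e-10)
  expect_equal(fit$intercept, 6.6, tolerance = 1e-10)
  expect_equal(fit$sigma2, 0, tolerance = 1e-20)
  # adding immature records changes nothing in the regression
  imm <- rbind(tab, data.frame(species = "larva", bodyweight_g = 2.5e-4,
                               clearance = 292.3, clearance_unit = "nL/h",
                               mature = FALSE))
  fit2 <- suppressWarnings(fit_allometric(imm))
  expect_equal(coef(fit2$lm), coef(fit$lm))
  expect_error(fit_allometric(tab[1:2, ]), "at least 3 mature")
})

test_that("regression is equivariant under a common clearance rescaling", {
  tab <- make_species(9, sigma = 0.2, seed = 42)
  fit <- fit_allometric(tab)
  tab2 <- tab
  tab2$clearance <- tab$clearance * 250
  fit2 <- fit_allometric(tab2)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-12)
  expect_equal(fit2$intercept, fit$intercept + log10(250), tolerance = 1e-12)
})

test_that("declared units are harmonised before fitting", {
  tab <- make_species(6, sigma = 0.1, seed = 8)
  tab_ml <- tab
  tab_ml$clearance <- tab$clearance / 1e6 # same values expressed in mL/h
  tab_ml$clearance_unit <- "mL/h"
  expect_equal(coef(fit_allometric(tab_ml)$lm), coef(fit_allometric(tab)$lm),
               tolerance = 1e-12)
  tab_bad <- tab; tab_bad$clearance_unit <- "furlong/fortnight"
  expect_error(fit_allometric(tab_bad), "unknown clearance unit")
})

test_that("the confidence band covers the true line at about its nominal rate", {
  hits <- 0L
  reps <- 300L
  x0 <- 100 # g, inside the fitted bodyweight range
  true_log_cl <- 6.6 + 0.75 * log10(x0)
  set.seed(2024)
  for (r in seq_len(reps)) {
    fit <- fit_allometric(make_species(10, sigma = 0.15))
    band <- predict(fit, bodyweight_g = x0)
    if (10^true_log_cl >= band$lwr && 10^true_log_cl <= band$upr)
      hits <- hits + 1L
  }
  coverage <- hits / reps
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.99)
})

test_that("larval clearance sits below the extrapolated mature band, quantified as a percentage", {
  fit <- fit_allometric(make_species(10, sigma = 0.1, seed = 3))
  volumes <- c(253, 263, 300)
  ke <- c(0.0193, 0.0226, 0.0266)
  cl <- clearance(ke, volumes)
  bw <- bodyweight_from_volume(volumes)
  pct <- fraction_of_lower_bound(cl, bw, fit)
  expect_true(all(pct < 100)) # below the lower bound of the band
  expect_true(all(diff(pct) > 0)) # older larvae approach the mature line
  expect_true(all(attr(pct, "extrapolated")))
  # exactness and linearity of the percentage
  band <- predict(fit, bodyweight_g = bw[1])
  expect_equal(fraction_of_lower_bound(band$lwr, bw[1], fit),
               100, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(as.numeric(fraction_of_lower_bound(2 * cl[1], bw[1], fit)),
               2 * as.numeric(pct[1]))
})
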