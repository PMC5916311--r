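test_that("endpoint estimator is the log-density ratio over elapsed time", {
  # two-point series 1e5 -> 1e6 over 5 days
  est <- fit_growth_rate(c(0, 5), c(1e5, 1e6), method = "endpoint")
  expect_equal(est$r, log(10) / 5, tolerance = 1e-12)
  expect_equal(fit_growth_rate(0:5, rep(4e5, 6), method = "endpoint")$r, 0)
})

test_that("both estimators recover the generating rate exactly, with or without dilution", {
  for (r in c(0.1, 0.3, 0.6)) {
    p <- one_species_panel(r = r)
    for (regime in c("batch", "semicontinuous")) {
      d <- culture_design(regime)
      s <- simulate_culture(p, d, "ambient")
      for (m in c("log_linear_regression", "endpoint")) {
        est <- fit_growth_rate(s$day, s$density, method = m,
                               dilution_schedule = dilution_events(d))
        expect_equal(est$r, r, tolerance = 1e-9)
      }
    }
  }
})

test_that("regression slope and standard error match stats::lm", {
  set.seed(7)
  day <- 0:5
  dens <- 1e5 * exp(0.4 * day + rnorm(6, 0, 0.05))
  est <- fit_growth_rate(day, dens)
  ref <- summary(lm(log(dens) ~ day))$coefficients
  expect_equal(est$r, ref["day", "Estimate"])
  expect_equal(est$standard_error, ref["day", "Std. Error"])
  expect_equal(est$n_points, 6L)
})

test_that("estimation errors name the offending time point", {
  expect_error(fit_growth_rate(0:2, c(1e5, 0, 2e5)), "day 1")
  expect_error(fit_growth_rate(0, 1e5), "at least 2 time points")
  expect_error(fit_growth_rate(0:1, c(1, 2, 3)), "equal length")
})

test_that("growth response is the high-minus-ambient rate difference", {
  a <- fit_growth_rate(c(0, 5), 1e5 * exp(0.38 * c(0, 5)), method = "endpoint")
  h <- fit_growth_rate(c(0, 5), 1e5 * exp(0.50 * c(0, 5)), method = "endpoint")
  expect_equal(growth_response(h, a)$delta_r, 0.12, tolerance = 1e-12)
  expect_equal(growth_response(a, a)$delta_r, 0)
  expect_equal(growth_response(a, h)$delta_r, -growth_response(h, a)$delta_r)

  hi <- tibble::tibble(species = "A", regime = "batch", r = 0.5,
                       standard_error = 0.03)
  lo <- tibble::tibble(species = "B", regime = "batch", r = 0.4,
                       standard_error = 0.04)
  expect_error(growth_response(hi, lo), "species mismatch")
  lo$species <- "A"; lo$regime <- "semicontinuous"
  expect_error(growth_response(hi, lo), "regime mismatch")
  lo$regime <- "batch"
  expect_equal(growth_response(hi, lo)$uncertainty, sqrt(0.03^2 + 0.04^2))
})

test_that("vectorized table fitting equals per-culture fitting, both methods", {
  ex <- generate_experiment(n_replicates = 2, seed = 21)
  scheds <- lapply(ex$designs, dilution_events)
  for (m in c("log_linear_regression", "endpoint")) {
    fits <- fit_growth_rates(ex, method = m)
    pure <- dplyr::filter(ex$data, culture_type == "pure")
    for (cid in sample(unique(pure$culture_id), 6)) {
      df <- pure[pure$culture_id == cid, ]
      ref <- fit_growth_rate(df$day, df$density_cells_per_ml, method = m,
                             dilution_schedule = scheds[[df$regime[1]]])
      row <- fits[fits$culture_id == cid, ]
      expect_equal(row$r, ref$r)
      expect_equal(row$standard_error, ref$standard_error)
    }
  }
})

test_that("noiseless pipeline recovers every rate; batch and semicontinuous agree", {
  ex <- generate_experiment(n_replicates = 1, noise = FALSE, seed = 1)
  fits <- fit_growth_rates(ex)
  truth <- ex$truth
  fits$r_true <- truth$r_ambient[match(fits$species, truth$name)] +
    (fits$co2 == "high") * truth$delta_r_co2[match(fits$species, truth$name)]
  expect_equal(fits$r, fits$r_true, tolerance = 1e-9)
  wide <- tidyr::pivot_wider(
    dplyr::select(fits, species, co2, regime, r),
    names_from = regime, values_from = r)
  expect_equal(wide$batch, wide$semicontinuous, tolerance = 1e-9)
})

test_that("per-species responses pool replicates and propagate uncertainty", {
  fits <- tibble::tibble(
    culture_id = paste0("c", 1:6),
    species = "A", regime = "batch",
    co2 = rep(c("ambient", "high"), each = 3),
    replicate = rep(1:3, 2), chamber = "C1",
    r = c(0.30, 0.32, 0.34, 0.40, 0.42, 0.44),
    standard_error = 0.01, n_points = 6L, method = "log_linear_regression"
  )
  resp <- growth_responses(fits)
  expect_equal(nrow(resp), 1)
  expect_equal(resp$delta_r, 0.10, tolerance = 1e-12)
  se <- sd(c(0.30, 0.32, 0.34)) / sqrt(3)
  expect_equal(resp$uncertainty, sqrt(2) * se)
  expect_error(growth_responses(fits[fits$co2 == "high", ]),
               "both ambient and high")
})
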