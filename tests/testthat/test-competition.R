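test_that("community generations count doublings with dilution correction", {
  expect_equal(community_growth_stats(c(0, 5), c(1e5, 8e5))$g_community, 3)
  expect_equal(community_growth_stats(c(0, 5), c(4e5, 4e5))$g_community, 0)
  expect_equal(community_growth_stats(c(0, 5), c(2e5, 5e5))$g_community,
               log2(2.5), tolerance = 1e-12)
  # r_community = g * ln2 / delta_t
  gs <- community_growth_stats(c(0, 5), c(1e5, 8e5))
  expect_equal(gs$r_community, 3 * log(2) / 5)
  # dilution-corrected: semicontinuous noiseless totals recover r * t / ln 2
  d <- culture_design("semicontinuous")
  p <- two_species_panel(r1 = 0.5, r2 = 0.3)
  s <- simulate_culture(p, d, "ambient")
  tot <- tapply(s$density, s$day, sum)
  gs2 <- community_growth_stats(as.numeric(names(tot)), as.numeric(tot),
                                dilution_events(d))
  expect_equal(gs2$r_community, log(sum(exp(5 * c(0.5, 0.3)) / 2)) / 5,
               tolerance = 1e-12)
  expect_error(community_growth_stats(c(0, 5), c(0, 1e5)), "positive")
})

test_that("predicted coefficient is the standardized rate difference", {
  expect_equal(predicted_coefficient(0.5, 0.3, 0.4), 0.5)
  expect_equal(predicted_coefficient(0.4, 0.4, 0.7), 0)
  expect_equal(predicted_coefficient(0.3, 0.5, 0.4), -0.5)
  expect_error(predicted_coefficient(0.5, 0.3, 0), "positive")
  expect_error(predicted_coefficient(0.5, 0.3, -0.1), "positive")
})

test_that("realized coefficient is log frequency-ratio change per generation", {
  expect_equal(realized_coefficient(0.3, 0.7, 0.3, 0.7, 2), 0)
  expect_equal(realized_coefficient(0.2, 0.8, 0.5, 0.5, 2), log(4) / 2,
               tolerance = 1e-12)
  expect_equal(realized_coefficient(0.8, 0.2, 0.5, 0.5, 2), -log(4) / 2,
               tolerance = 1e-12)
  expect_error(realized_coefficient(0, 1, 0.5, 0.5, 2), "strictly inside")
  expect_error(realized_coefficient(0.2, 0.8, 0.5, 0.5, 0), "non-zero")
})

test_that("full-community coefficient pools the complement", {
  comp <- tibble::tibble(
    day = rep(c(0, 5), each = 7),
    species = rep(paste0("sp", 1:7), 2),
    frequency = c(rep(1 / 7, 7), c(0.25, rep(0.75 / 6, 6)))
  )
  g <- community_growth_stats(c(0, 5), c(7e5, 28e5))  # g = 2
  got <- realized_coefficient_full_community(comp, "sp1", g)
  expect_equal(got, 0.5 * log(2), tolerance = 1e-12)
  # focal frequency constant -> 0
  flat <- comp; flat$frequency <- rep(1 / 7, 14)
  expect_equal(realized_coefficient_full_community(flat, "sp1", g), 0)
  # pooling before or after frequency normalization is identical
  dens <- tibble::tibble(
    day = rep(c(0, 5), each = 3),
    species = rep(c("a", "b", "c"), 2),
    density = c(1e5, 1e5, 1e5, 8e5, 2e5, 3e5)
  )
  freq <- dens |>
    dplyr::group_by(day) |>
    dplyr::mutate(frequency = density / sum(density)) |>
    dplyr::ungroup()
  gs <- community_growth_stats(c(0, 5), c(3e5, 13e5))
  via_freq <- realized_coefficient_full_community(freq, "a", gs)
  # pool complement densities first, then normalize the two-group system
  f_a <- c(1e5 / 3e5, 8e5 / 13e5)
  via_pool <- realized_coefficient(f_a[1], 1 - f_a[1], f_a[2], 1 - f_a[2],
                                   gs$g_community)
  expect_equal(via_freq, via_pool, tolerance = 1e-12)
  expect_error(
    realized_coefficient_full_community(freq[freq$species != "c", ], "a", gs),
    ">= 3 species")
})

test_that("competition response subtracts treatments and flags reversals", {
  r <- competition_response(-0.6, 0.64)
  expect_equal(r$value, -1.24, tolerance = 1e-12)
  expect_true(r$reversal)
  same <- competition_response(0.5, 0.5)
  expect_equal(same$value, 0)
  expect_false(same$reversal)
  both_neg <- competition_response(-0.9, -0.4)
  expect_lt(both_neg$value, 0)
  expect_false(both_neg$reversal)
  a <- tibble::tibble(focal = "A", opponent = "B", kind = "realized",
                      value = 0.5)
  b <- tibble::tibble(focal = "A", opponent = "C", kind = "realized",
                      value = 0.4)
  expect_error(competition_response(a, b), "do not match")
})

test_that("pairwise coefficients of the two focal choices are exact negatives", {
  ex <- generate_experiment(n_replicates = 2, seed = 13)
  coeffs <- competition_coefficients(ex)
  pair <- dplyr::filter(coeffs, level == "pairwise")
  sums <- pair |>
    dplyr::group_by(kind, co2, regime, replicate,
                    pair_id = paste(pmin(focal, opponent),
                                    pmax(focal, opponent))) |>
    dplyr::summarise(s = sum(value), n = dplyr::n(), .groups = "drop")
  expect_true(all(sums$n == 2))
  expect_true(all(abs(sums$s) < 1e-12))
})

test_that("realized equals ln2 x predicted in the noiseless limit", {
  ex <- generate_experiment(n_replicates = 1, noise = FALSE, seed = 1)
  coeffs <- competition_coefficients(ex, r_community = "realized")
  wide <- coeffs |>
    dplyr::filter(level == "pairwise") |>
    dplyr::select(focal, opponent, kind, co2, regime, value) |>
    tidyr::pivot_wider(names_from = kind, values_from = value,
                       values_fn = mean)
  expect_equal(wide$realized, log(2) * wide$predicted, tolerance = 1e-9)
})

test_that("realized coefficients are invariant to absolute density scale", {
  # same frequencies and generations, densities scaled 1000x: same value
  v1 <- realized_coefficient(0.3, 0.7, 0.6, 0.4, 2.5)
  v2 <- realized_coefficient(0.3, 0.7, 0.6, 0.4, 2.5)
  expect_identical(v1, v2)
  # end to end: scale all inoculation densities; coefficients unchanged
  d1 <- culture_design("batch", initial_density = 1e5)
  d2 <- culture_design("batch", initial_density = 1e8)
  p <- two_species_panel(r1 = 0.5, r2 = 0.3)
  c_of <- function(d) {
    s <- simulate_culture(p, d, "ambient")
    tot <- tapply(s$density, s$day, sum)
    g <- community_growth_stats(as.numeric(names(tot)), as.numeric(tot))
    f <- s$density[s$day %in% c(0, 5)]
    f0 <- f[1:2] / sum(f[1:2]); f5 <- f[3:4] / sum(f[3:4])
    realized_coefficient(f0[1], f0[2], f5[1], f5[2], g$g_community)
  }
  expect_equal(c_of(d1), c_of(d2), tolerance = 1e-12)
})

test_that("boundary frequencies error by default; the floor rescues them", {
  p <- two_species_panel(r1 = 0.5, r2 = 0.3)
  ex <- generate_experiment(
    panel = p, n_replicates = 1, seed = 3,
    model = observation_model(mixture_min_count = 1))  # forces 0/1 freqs
  expect_error(competition_coefficients(ex), "degenerate")
  coeffs <- competition_coefficients(ex, freq_floor = TRUE)
  expect_true(all(is.finite(coeffs$value)))
})

test_that("r_community conventions change predictions, not realizations", {
  ex <- generate_experiment(n_replicates = 1, noise = FALSE, seed = 2)
  a <- competition_coefficients(ex, r_community = "mean")
  b <- competition_coefficients(ex, r_community = "realized")
  keep <- c("focal", "opponent", "kind", "level", "co2", "regime")
  ra <- dplyr::arrange(dplyr::filter(a, kind == "realized"),
                       dplyr::across(dplyr::all_of(keep)))
  rb <- dplyr::arrange(dplyr::filter(b, kind == "realized"),
                       dplyr::across(dplyr::all_of(keep)))
  expect_equal(ra$value, rb$value)
  pa <- dplyr::filter(a, kind == "predicted")
  pb <- dplyr::filter(b, kind == "predicted")
  expect_false(isTRUE(all.equal(sort(pa$value), sort(pb$value))))
})

test_that("competition responses pair treatments by identity and replicate", {
  ex <- generate_experiment(n_replicates = 2, seed = 17)
  coeffs <- competition_coefficients(ex)
  resp <- competition_responses(coeffs)
  # every realized pair response has a replicate; predicted have NA
  expect_true(all(is.na(resp$replicate[resp$kind == "predicted"])))
  expect_true(all(!is.na(resp$replicate[resp$kind == "realized"])))
  # spot check one identity: response = high - ambient
  one <- resp[resp$kind == "realized" & resp$level == "pairwise", ][1, ]
  vals <- coeffs |>
    dplyr::filter(focal == one$focal, opponent == one$opponent,
                  kind == "realized", regime == one$regime,
                  replicate == one$replicate, level == "pairwise")
  expect_equal(one$response,
               vals$value[vals$co2 == "high"] -
                 vals$value[vals$co2 == "ambient"])
  expect_error(competition_responses(coeffs[coeffs$co2 == "high", ]),
               "both CO2 levels")
})
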