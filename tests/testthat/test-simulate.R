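test_that("species panel validates its closed vocabularies", {
  expect_error(species_panel("a", "fungus", 0.5, 0, "flow_cytometer"),
               "taxon")
  expect_error(species_panel("a", "diatom", -0.1, 0, "flow_cytometer"),
               "r_ambient")
  expect_error(species_panel(c("a", "a"), "diatom", c(0.5, 0.5), 0,
                             "flow_cytometer"), "unique")
  expect_error(species_panel("a", "diatom", 0.5, 0, "abacus"),
               "counting_instrument")
})

test_that("default panel encodes the taxon-level CO2 response structure", {
  p <- default_species_panel()
  expect_equal(nrow(p), 7)
  expect_setequal(unique(p$taxon),
                  c("cyanobacteria", "chlorophyte", "diatom",
                    "coccolithophore"))
  by_taxon <- tapply(p$delta_r_co2, p$taxon, mean)
  expect_equal(unname(by_taxon["chlorophyte"]), 0.20)
  expect_equal(unname(by_taxon["cyanobacteria"]), 0.06)
  # intermediates strictly between the extremes
  expect_true(all(by_taxon[c("diatom", "coccolithophore")] > 0.06))
  expect_true(all(by_taxon[c("diatom", "coccolithophore")] < 0.20))
  # jitter option perturbs responses reproducibly
  pj <- default_species_panel(jitter_sd = 0.02, seed = 3)
  expect_false(any(pj$delta_r_co2 == p$delta_r_co2))
  expect_identical(pj, default_species_panel(jitter_sd = 0.02, seed = 3))
})

test_that("culture design validates dilution and sampling times", {
  expect_error(culture_design("batch", dilution = 2), NA)  # forced to 0
  expect_equal(culture_design("batch")$dilution, 0)
  expect_equal(culture_design("semicontinuous")$dilution, 1 / 8)
  expect_error(culture_design("semicontinuous", dilution = 1), "dilution")
  expect_error(culture_design("batch", sampling_days = c(1, 2)),
               "start at 0")
  expect_error(culture_design("batch", sampling_days = c(0, 2, 1)),
               "increasing")
})

test_that("noiseless growth follows the exponential closed form", {
  # zero growth: constant density
  p0 <- one_species_panel(r = 0)
  s0 <- simulate_culture(p0, culture_design("batch"), "ambient")
  expect_equal(s0$density, rep(1e5, 6))

  # one doubling per day: 8e5 at day 3
  p2 <- one_species_panel(r = log(2))
  s2 <- simulate_culture(p2, culture_design("batch"), "ambient")
  expect_equal(s2$density[s2$day == 3], 8e5)

  # semicontinuous, r = 0: day-1 sample still 1e5, then 7/8 after dilution
  sd0 <- simulate_culture(p0, culture_design("semicontinuous"), "ambient")
  expect_equal(sd0$density[sd0$day == 1], 1e5)
  expect_equal(sd0$density[sd0$day == 2], 8.75e4)

  expect_error(simulate_culture(p0[0, ], culture_design("batch"), "ambient"),
               "at least one species")
})

test_that("high CO2 adds the species' growth-rate shift", {
  p <- one_species_panel(r = 0.3, dr = 0.1)
  d <- culture_design("batch")
  amb <- simulate_culture(p, d, "ambient")
  high <- simulate_culture(p, d, "high")
  expect_equal(high$density[high$day == 5], 1e5 * exp(0.4 * 5))
  expect_equal(log(high$density / amb$density), 0.1 * amb$day)
})

test_that("dilution is species-blind: frequencies are conserved exactly", {
  p <- two_species_panel(r1 = 0.6, r2 = 0.2)
  batch <- simulate_culture(p, culture_design("batch"), "ambient")
  semi <- simulate_culture(p, culture_design("semicontinuous"), "ambient")
  freq_of <- function(df) {
    tot <- tapply(df$density, df$day, sum)
    df$density / tot[as.character(df$day)]
  }
  expect_equal(freq_of(semi), freq_of(batch), tolerance = 1e-14)
})

test_that("noiseless pairwise frequency ratio is log-linear with slope r1-r2", {
  p <- two_species_panel(r1 = 0.55, r2 = 0.35)
  for (regime in c("batch", "semicontinuous")) {
    s <- simulate_culture(p, culture_design(regime), "ambient")
    f1 <- s$density[s$species == p$name[1]]
    f2 <- s$density[s$species == p$name[2]]
    lr <- log(f1 / f2)  # frequency ratio equals density ratio
    slopes <- diff(lr) / diff(unique(s$day))
    expect_equal(slopes, rep(0.55 - 0.35, 5), tolerance = 1e-9)
  }
})

test_that("expectation-mode counts are exact expectations", {
  p <- two_species_panel(r1 = 0, r2 = 0)
  s <- tibble::tibble(
    day = c(0, 0), species = p$name, density = c(2.5e4, 7.5e4)
  )
  obs <- observe_counts(s, p, mode = "expected")
  expect_equal(obs$count, c(100, 300))      # frequencies 0.25/0.75, total 400
  expect_equal(sum(obs$frequency), 1)
  expect_equal(obs$density, c(2.5e4, 7.5e4))  # expectation mode is exact
})

test_that("stochastic counts have the right mean (Monte-Carlo)", {
  p <- one_species_panel()
  s <- tibble::tibble(day = 0, species = p$name, density = 1e5)
  m <- observation_model()  # analyzed volume 0.05 ml -> lambda = 5000
  counts <- vapply(seq_len(1e4), function(i) {
    observe_counts(s, p, model = m, seed = i)$count
  }, numeric(1))
  lambda <- 1e5 * 0.05
  se <- sqrt(lambda / 1e4)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("flow-cytometer event cap and hemocytometer floor shape counts", {
  m <- observation_model()
  pf <- one_species_panel(instrument = "flow_cytometer")
  ph <- one_species_panel(instrument = "hemocytometer")
  dense <- tibble::tibble(day = 0, species = pf$name, density = 1e7)
  sparse <- tibble::tibble(day = 0, species = pf$name, density = 1e4)
  expect_equal(observe_counts(dense, pf, mode = "expected")$count,
               m$flow_max_events)               # cap at 10,000 events
  expect_equal(observe_counts(sparse, ph, mode = "expected")$count,
               m$hemo_min_count)                # scan until >= 400 expected
  # observed density is unbiased under both effective volumes
  expect_equal(observe_counts(dense, pf, mode = "expected")$density, 1e7)
  expect_equal(observe_counts(sparse, ph, mode = "expected")$density, 1e4)
})

test_that("zero-density species get zero counts; zero totals are flagged", {
  p <- two_species_panel()
  s <- tibble::tibble(day = c(0, 0), species = p$name, density = c(1e5, 0))
  for (i in 1:5) {
    obs <- observe_counts(s, p, seed = i)
    expect_equal(obs$count[obs$species == p$name[2]], 0)
  }
  s0 <- tibble::tibble(day = c(0, 0), species = p$name, density = c(0, 0))
  obs0 <- observe_counts(s0, p, seed = 1)
  expect_true(all(obs0$zero_total))
  expect_true(all(obs0$count == 0))
})

test_that("experiment enumerates pure, pairwise and community cultures", {
  ex <- generate_experiment(n_replicates = 3, noise = FALSE, seed = 1)
  n_cult <- dplyr::n_distinct(ex$data$culture_id)
  expect_equal(n_cult, (7 + 21 + 1) * 4 * 3)  # 348
  counts <- ex$data |>
    dplyr::distinct(culture_id, culture_type) |>
    dplyr::count(culture_type)
  expect_equal(counts$n[counts$culture_type == "pure"], 7 * 4 * 3)
  expect_equal(counts$n[counts$culture_type == "pair"], 21 * 4 * 3)
  expect_equal(counts$n[counts$culture_type == "community"], 4 * 3)
})

test_that("same seed gives bitwise-identical experiments", {
  a <- generate_experiment(n_replicates = 2, seed = 99)
  b <- generate_experiment(n_replicates = 2, seed = 99)
  expect_identical(a$data, b$data)
  c <- generate_experiment(n_replicates = 2, seed = 100)
  expect_false(identical(a$data, c$data))
})

test_that("observed frequencies sum to one at every mixture time point", {
  ex <- generate_experiment(n_replicates = 2, seed = 5)
  sums <- ex$data |>
    dplyr::filter(culture_type != "pure") |>
    dplyr::group_by(culture_id, day) |>
    dplyr::summarise(s = sum(frequency), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
})
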