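#' Observation (counting) model parameters
#'
#' Free parameters of the counting-noise model used by [observe_counts()]:
#'
#' * flow cytometry: per-species counts are Poisson with mean
#'   `density x analyzed volume`; the analyzed volume shrinks at high density
#'   so that no more than `flow_max_events` events are expected per sample
#'   (the instrument stops recording at a fixed event total).
#' * hemocytometry (microscopy): Poisson counts over an analyzed volume that
#'   grows at low density so that at least `hemo_min_count` cells are expected
#'   (the operator scans chambers until enough cells are seen).
#' * mixtures (microscopy): species counts are multinomial over the true
#'   frequencies with a fixed total of `mixture_min_count` cells; the total
#'   density of the mixture is counted with the hemocytometer model.
#'
#' The per-sample analyzed flow volume is not a published instrument constant
#' and is exposed here as a free parameter.
#'
#' @param flow_volume_ml nominal flow-cytometer analyzed volume, ml.
#' @param flow_max_events event cap per flow-cytometry sample.
#' @param hemo_volume_ml nominal hemocytometer analyzed volume, ml.
#' @param hemo_min_count minimum expected cell count for hemocytometry.
#' @param mixture_min_count total cells counted per mixture sample.
#' @return A list of class `"observation_model"`.
#' @export
observation_model <- function(flow_volume_ml = 0.05, flow_max_events = 10000,
                              hemo_volume_ml = 0.004, hemo_min_count = 400,
                              mixture_min_count = 400) {
  stopifnot(flow_volume_ml > 0, flow_max_events >= 1, hemo_volume_ml > 0,
            hemo_min_count >= 1, mixture_min_count >= 1)
  structure(
    list(flow_volume_ml = flow_volume_ml, flow_max_events = flow_max_events,
         hemo_volume_ml = hemo_volume_ml, hemo_min_count = hemo_min_count,
         mixture_min_count = mixture_min_count),
    class = "observation_model"
  )
}

# effective analyzed volume (ml) for a single-species count at density d
analyzed_volume <- function(d, instrument, model) {
  if (instrument == "flow_cytometer") {
    ifelse(d > 0, pmin(model$flow_volume_ml, model$flow_max_events / d),
           model$flow_volume_ml)
  } else {
    ifelse(d > 0, pmax(model$hemo_volume_ml, model$hemo_min_count / d),
           model$hemo_volume_ml)
  }
}

#' Simulate one culture's density time series
#'
#' Density-independent exponential growth of each species between sampling
#' times: under high CO2 each species grows at `r_ambient + delta_r_co2`,
#' under ambient CO2 at `r_ambient`. In the semicontinuous regime every
#' density is multiplied by `1 - dilution` immediately after each daily sample
#' from day 1 onward (sample first, then dilute), so the day-`t` sample
#' reflects all dilution events strictly before `t`. Cultures are assumed to
#' stay in exponential growth for the whole assay window (no carrying
#' capacity).
#'
#' @param species_specs a [species_panel()] (or subset) with >= 1 species.
#' @param design a [culture_design()].
#' @param co2_level `"ambient"` or `"high"`.
#' @param noiseless if `TRUE` (default) return exact densities; if `FALSE`,
#'   pass the exact series through [observe_counts()] and return observed
#'   counts, frequencies and densities.
#' @param model an [observation_model()] (used when `noiseless = FALSE`).
#' @param seed integer seed for the observation draw (when `noiseless =
#'   FALSE`).
#' @return A tibble with columns `day`, `species`, `density` (cells/ml;
#'   exact), and for `noiseless = FALSE` also `count`, `frequency` and
#'   `density_obs`.
#' @examples
#' panel <- default_species_panel()
#' simulate_culture(panel[1, ], culture_design("batch"), "ambient")
#' @export
simulate_culture <- function(species_specs, design,
                             co2_level = c("ambient", "high"),
                             noiseless = TRUE, model = observation_model(),
                             seed = NULL) {
  co2_level <- match.arg(co2_level)
  stopifnot(inherits(design, "culture_design"))
  if (!is.data.frame(species_specs) || nrow(species_specs) == 0) {
    stop("`species_specs` must contain at least one species", call. = FALSE)
  }
  r <- species_specs$r_ambient +
    (co2_level == "high") * species_specs$delta_r_co2
  days <- design$sampling_days
  ev <- dilution_events(design)
  # (1 - dilution)^{number of events strictly before each sampling day}
  dil_factor <- vapply(days, function(t) prod(1 - ev$fraction[ev$day < t]),
                       numeric(1))
  dens <- design$initial_density *
    exp(outer(days, r)) * dil_factor  # days x species
  nsp <- nrow(species_specs)
  # day-major ordering: all species at day 0, then day 1, ...
  out <- tibble::new_tibble(list(
    day = rep(days, each = nsp),
    species = rep(species_specs$name, times = length(days)),
    density = as.numeric(t(dens))
  ), nrow = nsp * length(days))
  if (noiseless) return(out)
  obs <- observe_counts(out, species_specs, model = model, seed = seed)
  names(obs)[names(obs) == "density"] <- "density_obs"
  dplyr::left_join(out, obs, by = c("day", "species"))
}

#' Observe a culture through its counting instrument
#'
#' Converts exact densities into counts, frequencies and observed densities
#' under the counting-noise model of [observation_model()]. Pure (single
#' species) cultures use the species' own instrument; mixtures are counted by
#' microscopy as multinomial draws over the true frequencies with a fixed
#' total count, and the mixture's total density is counted with the
#' hemocytometer model. `mode = "expected"` returns exact expected counts
#' (deterministic; counts need not be integers).
#'
#' A time point with zero total density cannot be composition-sampled: all
#' counts are returned as zero and the row is flagged in `zero_total`.
#'
#' @param true_series tibble with columns `day`, `species`, `density` (exact
#'   cells/ml), one culture.
#' @param species_specs the [species_panel()] rows covering every species in
#'   `true_series` (provides the counting instrument).
#' @param model an [observation_model()].
#' @param mode `"stochastic"` (default) or `"expected"`.
#' @param seed optional integer seed; the caller's RNG state is restored on
#'   exit.
#' @return A tibble with columns `day`, `species`, `count`, `frequency`
#'   (per-day species frequencies summing to 1), `density` (observed
#'   cells/ml) and `zero_total`.
#' @export
observe_counts <- function(true_series, species_specs,
                           model = observation_model(),
                           mode = c("stochastic", "expected"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("day", "species", "density") %in% names(true_series)))
  sp <- unique(true_series$species)
  miss <- setdiff(sp, species_specs$name)
  if (length(miss)) {
    stop("no instrument model for species: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(true_series$density < 0)) {
    stop("densities must be non-negative", call. = FALSE)
  }
  if (!is.null(seed) && mode == "stochastic") {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  days <- sort(unique(true_series$day))
  nd <- length(days)
  if (length(sp) == 1L) {
    instrument <-
      species_specs$counting_instrument[match(sp, species_specs$name)]
    d <- true_series$density[order(true_series$day)]
    v <- analyzed_volume(d, instrument, model)
    lambda <- d * v
    count <- if (mode == "stochastic") rpois(length(lambda), lambda) else lambda
    dens_obs <- count / v
    return(tibble::new_tibble(list(
      day = days, species = rep(sp, nd), count = count,
      frequency = ifelse(count > 0, 1, NA_real_),
      density = dens_obs, zero_total = count == 0 & d == 0
    ), nrow = nd))
  }

  # mixture: multinomial composition + hemocytometer total density, per day
  nsp <- length(sp)
  wide <- matrix(0, nrow = nd, ncol = nsp, dimnames = list(NULL, sp))
  idx <- cbind(match(true_series$day, days), match(true_series$species, sp))
  wide[idx] <- true_series$density
  total_n <- model$mixture_min_count
  counts <- matrix(0, nrow = nd, ncol = nsp)
  freq <- matrix(NA_real_, nrow = nd, ncol = nsp)
  dens_obs <- matrix(0, nrow = nd, ncol = nsp)
  zero_total <- logical(nd)
  for (i in seq_len(nd)) {
    d <- wide[i, ]
    tot <- sum(d)
    if (tot <= 0) {
      zero_total[i] <- TRUE
      next
    }
    f <- d / tot
    ci <- if (mode == "stochastic") {
      as.numeric(rmultinom(1, total_n, f))
    } else {
      total_n * f
    }
    v <- analyzed_volume(tot, "hemocytometer", model)
    tot_obs <- if (mode == "stochastic") rpois(1, tot * v) / v else tot
    counts[i, ] <- ci
    freq[i, ] <- ci / total_n
    dens_obs[i, ] <- ci / total_n * tot_obs
  }
  tibble::new_tibble(list(
    day = rep(days, each = nsp), species = rep(sp, times = nd),
    count = as.numeric(t(counts)), frequency = as.numeric(t(freq)),
    density = as.numeric(t(dens_obs)),
    zero_total = rep(zero_total, each = nsp)
  ), nrow = nd * nsp)
}

# short stable code for a species name, e.g. "Dunaliella tertiolecta" -> "Dte"
species_code <- function(name) {
  vapply(strsplit(name, "[ .]+"), function(parts) {
    if (length(parts) >= 2) {
      paste0(substr(parts[1], 1, 1), substr(parts[2], 1, 2))
    } else {
      substr(parts[1], 1, 3)
    }
  }, character(1))
}

#' Generate a complete synthetic competition experiment
#'
#' Emits the full factorial experiment: for every condition (CO2 level x
#' culture regime) and replicate, all pure cultures (one per species), all
#' unordered pairwise mixtures, and one full-community culture inoculated with
#' every species at `initial_density`. With the default 7-species panel that
#' is 7 + 21 + 1 = 29 cultures per condition and replicate; with 2 CO2 levels,
#' 2 regimes and 12 replicates, 1,392 cultures. Replicates are spread over two
#' growth-chamber configurations (CO2 treatments swapped between chambers in
#' blocks of three replicates); chambers are pure metadata, with no simulated
#' chamber effect.
#'
#' All randomness flows from `seed` through a documented splitting scheme: the
#' observation draw of each culture uses a seed derived from the experiment
#' seed and a stable hash of the culture id, so identical seeds give bitwise
#' identical datasets and any subset of cultures is reproducible on its own.
#'
#' @param panel a [species_panel()]; default [default_species_panel()].
#' @param n_replicates replicates per condition (>= 1; default 3).
#' @param designs named list of [culture_design()]s, one per regime.
#' @param co2_levels character subset of `c("ambient", "high")`.
#' @param noise `TRUE` for stochastic counting noise, `FALSE` for exact
#'   expected observations.
#' @param model an [observation_model()].
#' @param seed integer experiment seed.
#' @return A list of class `"phyto_experiment"`: `data` (long tibble with
#'   columns `culture_id`, `culture_type`, `regime`, `co2`, `replicate`,
#'   `chamber`, `day`, `species`, `true_density`, `count`, `frequency`,
#'   `density_cells_per_ml`), `truth` (the panel), `designs`,
#'   `model`, `n_replicates`, `noise` and `seed`.
#' @examples
#' ex <- generate_experiment(n_replicates = 1, seed = 7)
#' dplyr::n_distinct(ex$data$culture_id)  # 29 cultures x 4 conditions
#' @export
generate_experiment <- function(panel = default_species_panel(),
                                n_replicates = 3,
                                designs = list(
                                  batch = culture_design("batch"),
                                  semicontinuous = culture_design("semicontinuous")
                                ),
                                co2_levels = c("ambient", "high"),
                                noise = TRUE, model = observation_model(),
                                seed = 1L) {
  stopifnot(n_replicates >= 1, length(co2_levels) >= 1)
  co2_levels <- match.arg(co2_levels, c("ambient", "high"), several.ok = TRUE)
  if (is.null(names(designs)) || !all(nzchar(names(designs)))) {
    stop("`designs` must be a named list of culture_design objects",
         call. = FALSE)
  }
  nsp <- nrow(panel)
  codes <- species_code(panel$name)
  sets <- c(
    lapply(seq_len(nsp), identity),                       # pure
    if (nsp >= 2) utils::combn(nsp, 2, simplify = FALSE), # pairs
    if (nsp >= 3) list(seq_len(nsp))                      # full community
  )
  set_type <- vapply(sets, function(s) {
    if (length(s) == 1) "pure" else if (length(s) == nsp) "community" else "pair"
  }, character(1))
  set_label <- vapply(seq_along(sets), function(i) {
    if (set_type[i] == "community") "community"
    else paste(codes[sets[[i]]], collapse = "-")
  }, character(1))

  rows <- vector("list",
                 length(designs) * length(co2_levels) * n_replicates *
                   length(sets))
  k <- 0L
  for (regime in names(designs)) {
    design <- designs[[regime]]
    for (co2 in co2_levels) {
      for (rep_i in seq_len(n_replicates)) {
        config <- ((rep_i - 1) %/% 3) %% 2
        chamber <- if ((co2 == "ambient") == (config == 0)) "C1" else "C2"
        for (si in seq_along(sets)) {
          specs <- panel[sets[[si]], ]
          cid <- sprintf("%s_%s_%s_%s_r%02d", substr(regime, 1, 4), co2,
                         set_type[si], set_label[si], rep_i)
          true <- simulate_culture(specs, design, co2, noiseless = TRUE)
          if (noise) {
            obs <- observe_counts(true, specs, model = model,
                                  seed = split_seed(seed, cid))
          } else {
            obs <- observe_counts(true, specs, model = model,
                                  mode = "expected")
          }
          k <- k + 1L
          n <- nrow(true)
          # observe_counts preserves the day-major ordering of the series
          stopifnot(identical(obs$day, true$day),
                    identical(obs$species, true$species))
          rows[[k]] <- tibble::new_tibble(list(
            culture_id = rep(cid, n), culture_type = rep(set_type[si], n),
            regime = rep(regime, n), co2 = rep(co2, n),
            replicate = rep(rep_i, n), chamber = rep(chamber, n),
            day = true$day, species = true$species,
            true_density = true$density, count = obs$count,
            frequency = obs$frequency,
            density_cells_per_ml = obs$density
          ), nrow = n)
        }
      }
    }
  }
  structure(
    list(data = dplyr::bind_rows(rows), truth = panel, designs = designs,
         model = model, n_replicates = n_replicates, noise = noise,
         seed = as.integer(seed)),
    class = "phyto_experiment"
  )
}

#' @export
print.phyto_experiment <- function(x, ...) {
  cat(sprintf(
    "<phyto_experiment> %d cultures (%d species, %d replicate(s), %s)\n",
    dplyr::n_distinct(x$data$culture_id), nrow(x$truth), x$n_replicates,
    if (x$noise) "with counting noise" else "noiseless"))
  cat(sprintf("  seed %d; regimes: %s; rows: %d\n", x$seed,
              paste(names(x$designs), collapse = ", "), nrow(x$data)))
  invisible(x)
}
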