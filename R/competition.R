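#' Community growth statistics: generations and realized rate
#'
#' The number of community generations over an assay is the number of
#' doublings of total community density, corrected for known dilutions:
#' `g = (ln(total_final / total_initial) + sum(ln(1/(1 - fraction)))) / ln 2`,
#' summing over dilution events inside the window. The realized community
#' growth rate is `r_community = g * ln 2 / delta_t` (per day).
#'
#' @param days sampling times (days); the first and last are used.
#' @param totals total community densities (cells/ml) at `days`, positive at
#'   the endpoints.
#' @param dilution_schedule optional data frame (`day`, `fraction`) of
#'   dilution events; `NULL` for batch cultures.
#' @return A list of class `"generations_count"`: `g_community` (doublings),
#'   `r_community` (per day), `delta_t` (days).
#' @examples
#' community_growth_stats(c(0, 5), c(1e5, 8e5))$g_community  # 3 doublings
#' @export
community_growth_stats <- function(days, totals, dilution_schedule = NULL) {
  if (length(days) != length(totals) || length(days) < 2) {
    stop("`days` and `totals` must be equal length with >= 2 points",
         call. = FALSE)
  }
  ord <- order(days)
  days <- days[ord]; totals <- totals[ord]
  n <- length(days)
  if (!is.finite(totals[1]) || !is.finite(totals[n]) ||
      totals[1] <= 0 || totals[n] <= 0) {
    stop("total density must be positive at the first and last sampling",
         call. = FALSE)
  }
  corr <- dilution_correction(c(days[1], days[n]), dilution_schedule)
  delta_t <- days[n] - days[1]
  g <- (log(totals[n] / totals[1]) + corr[2] - corr[1]) / log(2)
  structure(
    list(g_community = g, r_community = g * log(2) / delta_t,
         delta_t = delta_t),
    class = "generations_count"
  )
}

#' @export
print.generations_count <- function(x, ...) {
  cat(sprintf("<generations_count> g = %.4f doublings over %g d (r = %.4f /day)\n",
              x$g_community, x$delta_t, x$r_community))
  invisible(x)
}

#' Predicted competition coefficient from pure-culture growth rates
#'
#' The predicted coefficient of a focal species against an opponent is the
#' difference of their pure-culture growth rates standardized by the growth
#' rate of the whole competing community:
#' `c_p = (r_focal - r_opponent) / r_community`. Positive values mean the
#' focal species is expected to gain on its opponent; a sign change between
#' treatments indicates a predicted dominance reversal.
#'
#' @param r_focal,r_opponent pure-culture growth rates (per day).
#' @param r_community community growth rate used for standardization (per
#'   day, > 0); see [competition_coefficients()] for the conventions offered.
#' @return The dimensionless coefficient.
#' @examples
#' predicted_coefficient(0.5, 0.3, 0.4)  # 0.5
#' @export
predicted_coefficient <- function(r_focal, r_opponent, r_community) {
  if (any(!is.finite(r_community)) || any(r_community <= 0)) {
    stop("`r_community` must be positive: the predicted coefficient is ",
         "undefined for a non-growing community", call. = FALSE)
  }
  (r_focal - r_opponent) / r_community
}

#' Realized competition coefficient from frequency change
#'
#' The realized coefficient of species 1 against species 2 is the change in
#' their log frequency ratio per community generation:
#' `c_r = (1/g) * ln((f1_final/f2_final) / (f1_initial/f2_initial))`,
#' with `g` the community generations over the window (see
#' [community_growth_stats()]). It depends only on frequencies and `g`, not on
#' the absolute density scale, and is antisymmetric in the two species.
#'
#' @param f1_initial,f2_initial,f1_final,f2_final frequencies strictly inside
#'   (0, 1).
#' @param g_community community generations (doublings), non-zero.
#' @return The dimensionless coefficient (per community generation).
#' @examples
#' realized_coefficient(0.2, 0.8, 0.5, 0.5, g_community = 2)  # ln(4)/2
#' @export
realized_coefficient <- function(f1_initial, f2_initial, f1_final, f2_final,
                                 g_community) {
  fs <- c(f1_initial, f2_initial, f1_final, f2_final)
  if (any(!is.finite(fs)) || any(fs <= 0) || any(fs >= 1)) {
    stop("frequencies must be strictly inside (0, 1); zero or boundary ",
         "frequencies are degenerate (apply a documented frequency floor ",
         "first if appropriate)", call. = FALSE)
  }
  if (any(!is.finite(g_community)) || any(g_community == 0)) {
    stop("`g_community` must be non-zero: the realized coefficient is ",
         "undefined without community growth", call. = FALSE)
  }
  (1 / g_community) *
    log((f1_final / f2_final) / (f1_initial / f2_initial))
}

#' Realized coefficient of one species against the pooled community
#'
#' In a full community the opponent frequency is the pooled complement
#' `f2 = 1 - f_focal` at each endpoint; otherwise as
#' [realized_coefficient()]. Pooling the complement before or after frequency
#' normalization gives identical results.
#'
#' @param composition tibble with columns `day`, `species`, `frequency` for
#'   one mixture culture with >= 3 species.
#' @param focal_species the focal species name.
#' @param generations a `"generations_count"` (or a bare number of doublings).
#' @return The dimensionless coefficient.
#' @export
realized_coefficient_full_community <- function(composition, focal_species,
                                                generations) {
  stopifnot(all(c("day", "species", "frequency") %in% names(composition)))
  sp <- unique(composition$species)
  if (length(sp) < 3) {
    stop("a full-community coefficient needs >= 3 species (use ",
         "realized_coefficient() for pairs)", call. = FALSE)
  }
  if (!focal_species %in% sp) {
    stop("focal species `", focal_species, "` not present", call. = FALSE)
  }
  g <- if (inherits(generations, "generations_count")) {
    generations$g_community
  } else {
    generations
  }
  days <- range(composition$day)
  f <- vapply(days, function(d) {
    composition$frequency[composition$day == d &
                            composition$species == focal_species][1]
  }, numeric(1))
  realized_coefficient(f[1], 1 - f[1], f[2], 1 - f[2], g)
}

#' CO2 response of a competition coefficient
#'
#' The response is the high-CO2 coefficient minus the ambient coefficient for
#' the same focal/opponent/kind. A sign change of the coefficient between
#' treatments is flagged as a competitive dominance reversal; a change that
#' keeps the sign only alters the speed of competitive exclusion.
#'
#' @param c_high,c_ambient coefficients: bare numbers, or one-row data frames
#'   with columns `value` and any of `focal`, `opponent`, `kind` (label
#'   mismatches error).
#' @return A list of class `"competition_response"`: `value`, `reversal`.
#' @examples
#' competition_response(-0.6, 0.64)  # value -1.24, reversal TRUE
#' @export
competition_response <- function(c_high, c_ambient) {
  grab <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(nrow(x) == 1, "value" %in% names(x))
      labs <- intersect(c("focal", "opponent", "kind"), names(x))
      list(value = x$value, labels = unlist(x[labs]))
    } else {
      list(value = as.numeric(x), labels = NULL)
    }
  }
  h <- grab(c_high); a <- grab(c_ambient)
  if (!is.null(h$labels) && !is.null(a$labels) &&
      !identical(h$labels, a$labels)) {
    stop("coefficient identities do not match: ",
         paste(h$labels, collapse = "/"), " vs ",
         paste(a$labels, collapse = "/"), call. = FALSE)
  }
  structure(
    list(value = h$value - a$value,
         reversal = (h$value != 0 && a$value != 0 &&
                       sign(h$value) != sign(a$value))),
    class = "competition_response"
  )
}

#' @export
print.competition_response <- function(x, ...) {
  cat(sprintf("<competition_response> %.4g%s\n", x$value,
              if (x$reversal) " (dominance reversal)" else ""))
  invisible(x)
}

# frequency floor for zero/boundary mixture frequencies:
# min(1/(2 * total count), 1e-4), applied symmetrically at both boundaries
apply_freq_floor <- function(f, total_count) {
  eps <- pmin(1 / (2 * total_count), 1e-4)
  pmin(pmax(f, eps), 1 - eps)
}

#' Competition coefficients for a whole experiment
#'
#' Computes the full coefficient table for an experiment: predicted
#' coefficients from mean pure-culture growth rates (one per species pair x
#' condition, and one per species against the pooled community), and realized
#' coefficients from endpoint frequency change per community generation (one
#' per mixture culture x focal species).
#'
#' Predicted coefficients use pure-culture information only. The
#' standardizing `r_community` convention is configurable:
#' `"mean"` (default) is the unweighted mean of the pure rates of the species
#' in the culture; `"density_weighted"` weights by inoculation density
#' (identical to `"mean"` under equal inoculation); `"realized"` uses the
#' realized total-density growth rate of the matching mixture cultures
#' (averaged over replicates) -- the convention under which noiseless realized
#' coefficients equal `ln 2` times predicted ones.
#'
#' Realized coefficients use observed frequencies at the first and last
#' sampling day and the dilution-corrected community generations from observed
#' total densities. Zero/boundary frequencies error unless `freq_floor =
#' TRUE`, which applies the documented floor `min(1/(2 * total count), 1e-4)`.
#'
#' @param experiment a `"phyto_experiment"` or compatible long table (then
#'   `designs` is required).
#' @param growth_fits optional precomputed [fit_growth_rates()] table;
#'   computed on the fly (regression method) when `NULL`.
#' @param r_community `"mean"`, `"density_weighted"` or `"realized"`.
#' @param freq_floor apply the frequency floor instead of erroring on
#'   boundary frequencies (default `FALSE`).
#' @param designs named list of [culture_design()] per regime (taken from the
#'   experiment object when available).
#' @return A tibble with columns `focal`, `opponent` (species name, or
#'   `"all_others"` for community rows), `kind` (`"predicted"`/`"realized"`),
#'   `level` (`"pairwise"`/`"community"`), `co2`, `regime`, `replicate`
#'   (`NA` for predicted), `g_community` (`NA` for predicted), `value`.
#' @export
competition_coefficients <- function(experiment, growth_fits = NULL,
                                     r_community = c("mean",
                                                     "density_weighted",
                                                     "realized"),
                                     freq_floor = FALSE, designs = NULL) {
  r_community <- match.arg(r_community)
  if (inherits(experiment, "phyto_experiment")) {
    data <- experiment$data
    designs <- experiment$designs
  } else {
    data <- experiment
    if (is.null(designs)) {
      stop("`designs` must be supplied when `experiment` is a plain table",
           call. = FALSE)
    }
  }
  if (is.null(growth_fits)) {
    growth_fits <- fit_growth_rates(data, designs = designs)
  }
  schedules <- lapply(designs, dilution_events)

  # ---- realized coefficients (also provides realized r_community) ----------
  mix <- dplyr::filter(data, .data$culture_type %in% c("pair", "community"))
  realized <- NULL
  mix_rates <- NULL
  if (nrow(mix) > 0) {
    ends <- mix |>
      dplyr::group_by(.data$culture_id) |>
      dplyr::filter(.data$day %in% range(.data$day)) |>
      dplyr::mutate(end = ifelse(.data$day == min(.data$day),
                                 "initial", "final")) |>
      dplyr::ungroup()
    gtab <- ends |>
      dplyr::group_by(.data$culture_id, .data$culture_type, .data$co2,
                      .data$regime, .data$replicate, .data$end,
                      .data$day) |>
      dplyr::summarise(total = sum(.data$density_cells_per_ml),
                       .groups = "drop") |>
      dplyr::group_by(.data$culture_id, .data$culture_type, .data$co2,
                      .data$regime, .data$replicate) |>
      dplyr::summarise(
        g_community = community_growth_stats(
          .data$day, .data$total,
          schedules[[.data$regime[1]]])$g_community,
        r_realized = community_growth_stats(
          .data$day, .data$total,
          schedules[[.data$regime[1]]])$r_community,
        .groups = "drop"
      )
    mix_rates <- gtab

    freqs <- ends |>
      dplyr::select("culture_id", "culture_type", "co2", "regime",
                    "replicate", "species", "end", "frequency", "count") |>
      dplyr::left_join(dplyr::select(gtab, "culture_id", "g_community"),
                       by = "culture_id")

    total_counts <- freqs |>
      dplyr::group_by(.data$culture_id, .data$end) |>
      dplyr::summarise(total_count = sum(.data$count), .groups = "drop")
    freqs <- dplyr::left_join(freqs, total_counts,
                              by = c("culture_id", "end"))
    boundary <- !is.finite(freqs$frequency) | freqs$frequency <= 0 |
      freqs$frequency >= 1
    if (any(boundary)) {
      if (!freq_floor) {
        bad <- unique(freqs$culture_id[boundary])
        stop("degenerate (0 or 1) species frequency in culture(s): ",
             paste(utils::head(bad, 5), collapse = ", "),
             if (length(bad) > 5) ", ..." else "",
             "; rerun with `freq_floor = TRUE` to apply the documented floor",
             call. = FALSE)
      }
      freqs$frequency <- ifelse(
        boundary,
        apply_freq_floor(ifelse(is.finite(freqs$frequency),
                                freqs$frequency, 0), freqs$total_count),
        freqs$frequency)
    }

    wide <- freqs |>
      dplyr::select("culture_id", "culture_type", "co2", "regime",
                    "replicate", "g_community", "species", "end",
                    "frequency") |>
      tidyr::pivot_wider(names_from = "end", values_from = "frequency")

    pair_wide <- dplyr::filter(wide, .data$culture_type == "pair")
    realized_pair <- NULL
    if (nrow(pair_wide) > 0) {
      realized_pair <- pair_wide |>
        dplyr::group_by(.data$culture_id, .data$co2, .data$regime,
                        .data$replicate, .data$g_community) |>
        dplyr::reframe(
          focal = .data$species,
          opponent = rev(.data$species),
          value = realized_coefficient(
            .data$initial, rev(.data$initial),
            .data$final, rev(.data$final), .data$g_community[1])
        ) |>
        dplyr::mutate(kind = "realized", level = "pairwise")
    }
    comm_wide <- dplyr::filter(wide, .data$culture_type == "community")
    realized_comm <- NULL
    if (nrow(comm_wide) > 0) {
      realized_comm <- comm_wide |>
        dplyr::mutate(
          focal = .data$species, opponent = "all_others",
          value = realized_coefficient(
            .data$initial, 1 - .data$initial,
            .data$final, 1 - .data$final, .data$g_community),
          kind = "realized", level = "community"
        ) |>
        dplyr::select(-"species", -"culture_type", -"initial", -"final")
    }
    realized <- dplyr::bind_rows(realized_pair, realized_comm) |>
      dplyr::select("focal", "opponent", "kind", "level", "co2", "regime",
                    "replicate", "g_community", "value")
  }

  # ---- predicted coefficients ----------------------------------------------
  rbar <- growth_fits |>
    dplyr::group_by(.data$species, .data$co2, .data$regime) |>
    dplyr::summarise(r = mean(.data$r), .groups = "drop")
  conds <- dplyr::distinct(rbar, .data$co2, .data$regime)
  species <- sort(unique(rbar$species))
  predicted <- vector("list", 0)
  for (ci in seq_len(nrow(conds))) {
    co2 <- conds$co2[ci]; regime <- conds$regime[ci]
    rr <- rbar[rbar$co2 == co2 & rbar$regime == regime, ]
    rv <- setNames(rr$r, rr$species)
    realized_rate <- function(type, id_species = NULL) {
      if (is.null(mix_rates)) {
        stop("`r_community = \"realized\"` needs mixture cultures in the ",
             "experiment", call. = FALSE)
      }
      sub <- mix_rates[mix_rates$co2 == co2 & mix_rates$regime == regime &
                         mix_rates$culture_type == type, ]
      if (!is.null(id_species)) {
        want <- paste(sort(species_code(id_species)), collapse = "|")
        have <- vapply(strsplit(sub$culture_id, "_"), function(p) {
          paste(sort(strsplit(p[4], "-")[[1]]), collapse = "|")
        }, character(1))
        sub <- sub[have == want, ]
      }
      mean(sub$r_realized)
    }
    pairs <- utils::combn(species, 2, simplify = FALSE)
    prs <- lapply(pairs, function(p) {
      rc <- switch(r_community,
        mean = mean(rv[p]),
        density_weighted = mean(rv[p]),  # equal inoculation densities
        realized = realized_rate("pair", p))
      v <- predicted_coefficient(rv[p[1]], rv[p[2]], rc)
      tibble::tibble(focal = p, opponent = rev(p), value = c(v, -v))
    })
    rc_all <- switch(r_community,
      mean = mean(rv),
      density_weighted = mean(rv),
      realized = realized_rate("community"))
    comm <- tibble::tibble(
      focal = species, opponent = "all_others",
      value = vapply(species, function(s) {
        predicted_coefficient(rv[s], mean(rv[setdiff(species, s)]), rc_all)
      }, numeric(1))
    )
    predicted[[ci]] <- dplyr::bind_rows(
      dplyr::bind_rows(prs) |> dplyr::mutate(level = "pairwise"),
      comm |> dplyr::mutate(level = "community")
    ) |>
      dplyr::mutate(kind = "predicted", co2 = co2, regime = regime,
                    replicate = NA_integer_, g_community = NA_real_)
  }
  predicted <- dplyr::bind_rows(predicted) |>
    dplyr::select("focal", "opponent", "kind", "level", "co2", "regime",
                  "replicate", "g_community", "value")

  dplyr::bind_rows(predicted, realized)
}

#' CO2 responses of competition coefficients
#'
#' Pairs high- and ambient-CO2 coefficients of matching identity (focal,
#' opponent, kind, level, regime and -- for realized coefficients -- replicate
#' index) and returns the per-pair response `high - ambient`. Dominance
#' reversals are flagged per identity group from the replicate-mean
#' coefficients.
#'
#' @param coefficients output of [competition_coefficients()] covering both
#'   CO2 levels.
#' @return A tibble: `focal`, `opponent`, `kind`, `level`, `regime`,
#'   `replicate`, `response`, `reversal`.
#' @export
competition_responses <- function(coefficients) {
  key <- c("focal", "opponent", "kind", "level", "regime", "replicate")
  high <- dplyr::filter(coefficients, .data$co2 == "high")
  amb <- dplyr::filter(coefficients, .data$co2 == "ambient")
  if (nrow(high) == 0 || nrow(amb) == 0) {
    stop("`coefficients` must contain both CO2 levels", call. = FALSE)
  }
  joined <- dplyr::inner_join(
    dplyr::select(high, dplyr::all_of(key), value_high = "value"),
    dplyr::select(amb, dplyr::all_of(key), value_ambient = "value"),
    by = key
  )
  joined |>
    dplyr::group_by(.data$focal, .data$opponent, .data$kind, .data$level,
                    .data$regime) |>
    dplyr::mutate(
      reversal = {
        mh <- mean(.data$value_high); ma <- mean(.data$value_ambient)
        mh != 0 && ma != 0 && sign(mh) != sign(ma)
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      .data$focal, .data$opponent, .data$kind, .data$level, .data$regime,
      .data$replicate, response = .data$value_high - .data$value_ambient,
      .data$reversal
    )
}
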