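# cumulative dilution correction: for each sampling time t, the sum of
# ln(1/(1 - fraction)) over dilution events strictly before t
dilution_correction <- function(days, dilution_schedule) {
  if (is.null(dilution_schedule) || nrow(dilution_schedule) == 0) {
    return(numeric(length(days)))
  }
  stopifnot(all(c("day", "fraction") %in% names(dilution_schedule)))
  vapply(days, function(t) {
    f <- dilution_schedule$fraction[dilution_schedule$day < t]
    -sum(log1p(-f))
  }, numeric(1))
}

#' Fit an exponential growth rate to one culture
#'
#' Estimates the per-day exponential rate from a daily density series, with a
#' correction for known dilution events (semicontinuous cultures): each
#' sampled log-density is raised by the cumulative `sum(ln(1/(1 - fraction)))`
#' of dilutions that happened before that sample, restoring the underlying
#' exponential trajectory.
#'
#' Two estimators are available. `"endpoint"` is the natural-log density ratio
#' between the first and last samples over the elapsed time (plus the dilution
#' correction); `"log_linear_regression"` (default) is the ordinary
#' least-squares slope of corrected ln-density on time, which uses all daily
#' points and yields a standard error. On noiseless exponential data the two
#' agree exactly.
#'
#' @param days numeric sampling times in days (>= 2 points).
#' @param densities cell densities (cells/ml), strictly positive.
#' @param method `"log_linear_regression"` (default) or `"endpoint"`.
#' @param dilution_schedule optional data frame of dilution events with
#'   columns `day` and `fraction` (see [dilution_events()]); `NULL` for batch.
#' @return A list of class `"growth_rate_estimate"`: `r` (per day), `method`,
#'   `standard_error` (per day; 0 for the endpoint method, which has no
#'   residual information), `n_points`.
#' @examples
#' fit_growth_rate(0:5, 1e5 * exp(0.3 * 0:5))
#' @export
fit_growth_rate <- function(days, densities,
                            method = c("log_linear_regression", "endpoint"),
                            dilution_schedule = NULL) {
  method <- match.arg(method)
  if (length(days) != length(densities)) {
    stop("`days` and `densities` must have equal length", call. = FALSE)
  }
  if (length(days) < 2) {
    stop("at least 2 time points are required to estimate a growth rate",
         call. = FALSE)
  }
  bad <- which(!is.finite(densities) | densities <= 0)
  if (length(bad)) {
    stop("non-positive density at day ",
         paste(days[bad], collapse = ", "),
         "; growth rates need strictly positive densities ",
         "(consider a density floor upstream)", call. = FALSE)
  }
  ord <- order(days)
  days <- days[ord]; densities <- densities[ord]
  ln_d <- log(densities) + dilution_correction(days, dilution_schedule)

  if (method == "endpoint") {
    n <- length(days)
    r <- (ln_d[n] - ln_d[1]) / (days[n] - days[1])
    se <- 0
    npts <- 2L
  } else {
    x <- days - mean(days)
    sxx <- sum(x^2)
    r <- sum(x * ln_d) / sxx
    resid <- ln_d - mean(ln_d) - r * x
    npts <- length(days)
    se <- if (npts > 2) sqrt(sum(resid^2) / (npts - 2) / sxx) else 0
  }
  structure(
    list(r = r, method = method, standard_error = se, n_points = npts),
    class = "growth_rate_estimate"
  )
}

#' @export
print.growth_rate_estimate <- function(x, ...) {
  cat(sprintf("<growth_rate_estimate> r = %.6g /day (se %.3g, %d points, %s)\n",
              x$r, x$standard_error, x$n_points, x$method))
  invisible(x)
}

#' Fit growth rates for every pure culture of an experiment
#'
#' Applies [fit_growth_rate()] culture by culture to the pure cultures of an
#' experiment table, deriving each culture's dilution schedule from its regime
#' design. Replicates are never pooled here; pooling happens at the response
#' stage ([growth_responses()]).
#'
#' @param experiment a `"phyto_experiment"` (from [generate_experiment()]) or
#'   a data frame with columns `culture_id`, `culture_type`, `regime`, `co2`,
#'   `replicate`, `chamber`, `day`, `species`, `density_cells_per_ml` (in
#'   which case `designs` must be supplied).
#' @param method passed to [fit_growth_rate()].
#' @param designs named list of [culture_design()] per regime; taken from the
#'   experiment object when available.
#' @param density_floor optional lower bound applied to densities before
#'   fitting (cells/ml); default `NULL` leaves zero densities to error, the
#'   documented behaviour.
#' @return A tibble with one row per pure culture: `culture_id`, `species`,
#'   `co2`, `regime`, `replicate`, `chamber`, `r`, `standard_error`,
#'   `n_points`, `method`.
#' @export
fit_growth_rates <- function(experiment,
                             method = c("log_linear_regression", "endpoint"),
                             designs = NULL, density_floor = NULL) {
  method <- match.arg(method)
  if (inherits(experiment, "phyto_experiment")) {
    designs <- experiment$designs
    data <- experiment$data
  } else {
    data <- experiment
    if (is.null(designs)) {
      stop("`designs` must be supplied when `experiment` is a plain table",
           call. = FALSE)
    }
  }
  pure <- dplyr::filter(data, .data$culture_type == "pure")
  if (nrow(pure) == 0) stop("no pure cultures in `experiment`", call. = FALSE)
  schedules <- lapply(designs, dilution_events)

  # per-regime cumulative dilution corrections, joined by sampling day
  corr_tab <- dplyr::bind_rows(lapply(names(schedules), function(reg) {
    d <- sort(unique(pure$day[pure$regime == reg]))
    tibble::tibble(regime = reg, day = d,
                   corr = dilution_correction(d, schedules[[reg]]))
  }))
  pure <- dplyr::left_join(pure, corr_tab, by = c("regime", "day"))
  dens <- pure$density_cells_per_ml
  if (!is.null(density_floor)) dens <- pmax(dens, density_floor)
  bad <- !is.finite(dens) | dens <= 0
  if (any(bad)) {
    stop("non-positive density in culture(s) ",
         paste(utils::head(unique(pure$culture_id[bad]), 5), collapse = ", "),
         " at day ", paste(utils::head(pure$day[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  pure$ln_d <- log(dens) + pure$corr

  # closed-form OLS slope / endpoint ratio per culture (identical to
  # fit_growth_rate(); the two paths are cross-checked in the test suite)
  pure |>
    dplyr::group_by(.data$culture_id, .data$species, .data$co2, .data$regime,
                    .data$replicate, .data$chamber) |>
    dplyr::summarise(
      r = if (method == "endpoint") {
        (.data$ln_d[which.max(.data$day)] - .data$ln_d[which.min(.data$day)]) /
          (max(.data$day) - min(.data$day))
      } else {
        sum((.data$day - mean(.data$day)) * .data$ln_d) /
          sum((.data$day - mean(.data$day))^2)
      },
      standard_error = if (method == "endpoint" || dplyr::n() <= 2) 0 else {
        sxx <- sum((.data$day - mean(.data$day))^2)
        res <- .data$ln_d - mean(.data$ln_d) -
          r * (.data$day - mean(.data$day))
        sqrt(sum(res^2) / (dplyr::n() - 2) / sxx)
      },
      n_points = if (method == "endpoint") 2L else dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(method = method)
}

#' CO2 growth response from a pair of growth-rate estimates
#'
#' The growth response is the high-CO2 growth rate minus the ambient-CO2
#' growth rate for the same species and regime; its uncertainty is the
#' root-sum-square of the two standard errors.
#'
#' @param r_high,r_ambient single growth-rate records: either
#'   `"growth_rate_estimate"` objects or one-row data frames with columns
#'   `species`, `regime`, `r`, `standard_error`. When both carry `species` /
#'   `regime` labels they must match.
#' @return A list of class `"growth_response"`: `species`, `regime`,
#'   `delta_r` (per day), `uncertainty`.
#' @examples
#' a <- fit_growth_rate(0:5, 1e5 * exp(0.38 * 0:5))
#' h <- fit_growth_rate(0:5, 1e5 * exp(0.50 * 0:5))
#' growth_response(h, a)$delta_r
#' @export
growth_response <- function(r_high, r_ambient) {
  grab <- function(x) {
    if (inherits(x, "growth_rate_estimate")) {
      list(species = NA_character_, regime = NA_character_, r = x$r,
           se = x$standard_error)
    } else if (is.data.frame(x) && nrow(x) == 1) {
      list(species = if ("species" %in% names(x)) x$species else NA_character_,
           regime = if ("regime" %in% names(x)) x$regime else NA_character_,
           r = x$r,
           se = if ("standard_error" %in% names(x)) x$standard_error else 0)
    } else {
      stop("growth-rate records must be growth_rate_estimate objects or ",
           "one-row data frames", call. = FALSE)
    }
  }
  h <- grab(r_high); a <- grab(r_ambient)
  if (!is.na(h$species) && !is.na(a$species) && h$species != a$species) {
    stop("species mismatch: ", h$species, " vs ", a$species, call. = FALSE)
  }
  if (!is.na(h$regime) && !is.na(a$regime) && h$regime != a$regime) {
    stop("regime mismatch: ", h$regime, " vs ", a$regime, call. = FALSE)
  }
  structure(
    list(species = h$species, regime = h$regime, delta_r = h$r - a$r,
         uncertainty = sqrt(h$se^2 + a$se^2)),
    class = "growth_response"
  )
}

#' Per-species CO2 growth responses from fitted rates
#'
#' Pools replicate pure-culture fits (chambers are treated as replicates):
#' for each species x regime, the response is the mean high-CO2 rate minus the
#' mean ambient rate, with uncertainty the root-sum-square of the two standard
#' errors of the means.
#'
#' @param fits output of [fit_growth_rates()] covering both CO2 levels.
#' @return A tibble: `species`, `regime`, `delta_r`, `uncertainty`,
#'   `n_high`, `n_ambient`.
#' @export
growth_responses <- function(fits) {
  need <- c("species", "regime", "co2", "r")
  miss <- setdiff(need, names(fits))
  if (length(miss)) {
    stop("`fits` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  summ <- fits |>
    dplyr::group_by(.data$species, .data$regime, .data$co2) |>
    dplyr::summarise(
      mean_r = mean(.data$r),
      se_mean = if (dplyr::n() > 1) sd(.data$r) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(), .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "co2",
                       values_from = c("mean_r", "se_mean", "n"))
  if (!all(c("mean_r_high", "mean_r_ambient") %in% names(summ))) {
    stop("`fits` must contain both ambient and high CO2 levels",
         call. = FALSE)
  }
  summ |>
    dplyr::transmute(
      .data$species, .data$regime,
      delta_r = .data$mean_r_high - .data$mean_r_ambient,
      uncertainty = sqrt(.data$se_mean_high^2 + .data$se_mean_ambient^2),
      n_high = .data$n_high, n_ambient = .data$n_ambient
    )
}
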