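#' Species-averaged response pairs for prediction
#'
#' Builds the per-species (x, y) table behind the headline regression: does a
#' species' growth response to CO2 predict its competitive response?
#'
#' At `level = "pairwise"` the response variable `y` is the focal species'
#' mean realized pairwise competitive response, averaged over all opponents
#' and replicates; at `level = "community"` it is the mean full-community
#' competitive response over replicates. The predictor `x` is by default the
#' species' pure-culture growth response (`predictor = "growth"`); for the
#' "pairwise predicts community" stage it is the mean realized pairwise
#' competitive response (`predictor = "pairwise"`); `predictor = "predicted"`
#' uses the mean predicted pairwise response, the natural x when comparing
#' realized against predicted competition. One record per species x regime.
#'
#' @param responses output of [competition_responses()].
#' @param growth_responses output of [growth_responses()] (required when
#'   `predictor = "growth"`).
#' @param level `"pairwise"` or `"community"`: which competitive responses
#'   form `y`.
#' @param predictor `"growth"`, `"pairwise"` or `"predicted"`: what forms
#'   `x`.
#' @return A tibble: `species`, `regime`, `x`, `y`, `n` (responses averaged
#'   into `y`), `dispersion` (their sd).
#' @export
species_mean_responses <- function(responses, growth_responses = NULL,
                                   level = c("pairwise", "community"),
                                   predictor = c("growth", "pairwise",
                                                 "predicted")) {
  level <- match.arg(level)
  predictor <- match.arg(predictor)

  mean_resp <- function(lv, knd = "realized") {
    responses |>
      dplyr::filter(.data$kind == knd, .data$level == lv) |>
      dplyr::group_by(species = .data$focal, .data$regime) |>
      dplyr::summarise(y = mean(.data$response), n = dplyr::n(),
                       dispersion = sd(.data$response), .groups = "drop")
  }
  ytab <- mean_resp(level)
  if (nrow(ytab) == 0) {
    stop("no realized ", level, " responses in `responses`", call. = FALSE)
  }

  if (predictor == "growth") {
    if (is.null(growth_responses)) {
      stop("`growth_responses` is required when `predictor = \"growth\"`",
           call. = FALSE)
    }
    xtab <- dplyr::select(growth_responses, "species", "regime",
                          x = "delta_r")
  } else if (predictor == "pairwise") {
    xtab <- mean_resp("pairwise") |>
      dplyr::select("species", "regime", x = "y")
  } else {
    xtab <- mean_resp(level, knd = "predicted") |>
      dplyr::select("species", "regime", x = "y")
  }
  out <- dplyr::inner_join(xtab, ytab, by = c("species", "regime"))
  missing <- setdiff(unique(xtab$species), unique(ytab$species))
  if (length(missing)) {
    stop("species without ", level, " responses: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(out, .data$regime, .data$species)
}

#' Fit the prediction regression
#'
#' Ordinary least squares of the competitive response `y` on the predictor
#' `x` across species, reporting descriptive quantities only (slope,
#' intercept, coefficient of determination); no significance testing.
#'
#' @param pairs a response-pair table from [species_mean_responses()] (or any
#'   data frame with numeric `x` and `y`), >= 3 rows.
#' @return A list of class `"prediction_fit"`: `slope`, `intercept`,
#'   `r_squared`, `n_points`, `residuals`.
#' @examples
#' fit_prediction(data.frame(x = 1:5, y = log(2) * (1:5)))
#' @export
fit_prediction <- function(pairs) {
  stopifnot(all(c("x", "y") %in% names(pairs)))
  x <- pairs$x; y <- pairs$y
  if (length(x) < 3) {
    stop("at least 3 species are needed to fit the prediction regression",
         call. = FALSE)
  }
  if (var(x) == 0) {
    stop("degenerate fit: the predictor `x` has zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, n_points = length(x),
         residuals = unname(stats::residuals(fit))),
    class = "prediction_fit"
  )
}

#' @export
print.prediction_fit <- function(x, ...) {
  cat(sprintf(
    "<prediction_fit> y = %.4g + %.4g x; R^2 = %.4f (n = %d species)\n",
    x$intercept, x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Prediction fits per level and regime
#'
#' Runs the prediction regression separately for each culture regime (the two
#' fitted lines of the standard presentation) and each requested level:
#' growth response predicting mean pairwise competitive response, growth
#' response predicting full-community response, and mean pairwise response
#' predicting community response.
#'
#' @param responses output of [competition_responses()].
#' @param growth_resp output of [growth_responses()].
#' @param levels character subset of `c("pairwise", "community",
#'   "pairwise_to_community")`.
#' @return A list with `summary` (tibble: `level`, `predictor`, `regime`,
#'   `slope`, `intercept`, `r_squared`, `n`) and `points` (the per-species
#'   scatter tables, one tibble with a `level` column, suitable for plotting).
#' @export
prediction_fits <- function(responses, growth_resp,
                            levels = c("pairwise", "community",
                                       "pairwise_to_community")) {
  levels <- match.arg(levels, several.ok = TRUE)
  spec <- list(
    pairwise = list(level = "pairwise", predictor = "growth"),
    community = list(level = "community", predictor = "growth"),
    pairwise_to_community = list(level = "community", predictor = "pairwise")
  )
  summaries <- list(); points <- list()
  for (lv in levels) {
    s <- spec[[lv]]
    tab <- species_mean_responses(responses, growth_resp,
                                  level = s$level, predictor = s$predictor)
    for (reg in unique(tab$regime)) {
      sub <- tab[tab$regime == reg, ]
      fit <- fit_prediction(sub)
      summaries[[paste(lv, reg)]] <- tibble::tibble(
        level = lv, predictor = s$predictor, regime = reg,
        slope = fit$slope, intercept = fit$intercept,
        r_squared = fit$r_squared, n = fit$n_points
      )
    }
    points[[lv]] <- dplyr::mutate(tab, level = lv)
  }
  list(summary = dplyr::bind_rows(summaries),
       points = dplyr::bind_rows(points))
}
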