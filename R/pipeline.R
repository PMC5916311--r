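#' Pipeline run configuration
#'
#' A fully serializable description of one end-to-end run: panel, design,
#' noise switches, method choices and seed. A run is reproducible bit for bit
#' from config + seed. Write/read with [write_run_config()] /
#' [read_run_config()].
#'
#' @param seed integer experiment seed (all randomness flows from it).
#' @param n_replicates replicates per condition.
#' @param noise simulate counting noise (`TRUE`) or exact expectations.
#' @param jitter_sd species-level jitter sd for the default panel (per day).
#' @param growth_method `"log_linear_regression"` or `"endpoint"`.
#' @param r_community standardization convention for predicted coefficients;
#'   see [competition_coefficients()].
#' @param freq_floor apply the documented frequency floor to boundary mixture
#'   frequencies instead of erroring.
#' @param co2_levels CO2 treatments to simulate.
#' @param duration_days,initial_density,dilution,volume_ml design parameters
#'   (see [culture_design()]); `dilution` applies to the semicontinuous
#'   regime only.
#' @param regimes culture regimes to simulate.
#' @param panel optional explicit [species_panel()]; default `NULL` uses
#'   [default_species_panel()] with `jitter_sd`.
#' @param observation named list of [observation_model()] overrides.
#' @param output_dir optional directory for tables/manifest (written by
#'   [run_pipeline()]).
#' @return A list of class `"run_config"`.
#' @export
pipeline_config <- function(seed = 1L, n_replicates = 3L, noise = TRUE,
                            jitter_sd = 0,
                            growth_method = c("log_linear_regression",
                                              "endpoint"),
                            r_community = c("mean", "density_weighted",
                                            "realized"),
                            freq_floor = FALSE,
                            co2_levels = c("ambient", "high"),
                            duration_days = 5, initial_density = 1e5,
                            dilution = 1 / 8, volume_ml = 8,
                            regimes = c("batch", "semicontinuous"),
                            panel = NULL, observation = list(),
                            output_dir = NULL) {
  growth_method <- match.arg(growth_method)
  r_community <- match.arg(r_community)
  regimes <- match.arg(regimes, c("batch", "semicontinuous"),
                       several.ok = TRUE)
  co2_levels <- match.arg(co2_levels, c("ambient", "high"),
                          several.ok = TRUE)
  structure(
    list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
         noise = isTRUE(noise), jitter_sd = jitter_sd,
         growth_method = growth_method, r_community = r_community,
         freq_floor = isTRUE(freq_floor), co2_levels = co2_levels,
         duration_days = duration_days, initial_density = initial_density,
         dilution = dilution, volume_ml = volume_ml, regimes = regimes,
         panel = if (is.null(panel)) NULL else as.data.frame(panel),
         observation = observation, output_dir = output_dir),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> seed %d, %d replicate(s)/condition, %s, method %s, r_community %s\n",
    x$seed, x$n_replicates,
    if (x$noise) "counting noise on" else "noiseless", x$growth_method,
    x$r_community))
  invisible(x)
}

#' Write / read a run configuration (YAML)
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   returns the reconstructed `"run_config"`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  if (!is.null(x$panel)) x$panel <- as.list(as.data.frame(x$panel))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$panel)) {
    x$panel <- do.call(species_panel, x$panel[c(
      "name", "taxon", "r_ambient", "delta_r_co2", "counting_instrument")])
  }
  if (!is.null(x$output_dir) && !nzchar(x$output_dir)) x$output_dir <- NULL
  do.call(pipeline_config, x)
}

run_designs <- function(config) {
  designs <- lapply(config$regimes, function(reg) {
    culture_design(reg, volume_ml = config$volume_ml,
                   duration_days = config$duration_days,
                   initial_density = config$initial_density,
                   dilution = if (reg == "semicontinuous") config$dilution
                              else 0)
  })
  names(designs) <- config$regimes
  designs
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> observe -> growth fits -> growth responses ->
#' competition coefficients -> competition responses -> prediction fits, plus
#' a ground-truth comparison of every simulated growth parameter, and a
#' machine-readable manifest (package version, seed, per-stage row counts).
#' With an `output_dir` set, all tables are written as schema-headed CSV
#' ([write_phyto_table()]) together with `manifest.json` and `config.yaml`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return A list of class `"phyto_run"`: `experiment`, `growth_fits`,
#'   `growth_responses`, `coefficients`, `responses`, `prediction`
#'   (summary + points), `recovery`, `manifest`, `config`.
#' @examples
#' run <- run_pipeline(pipeline_config(seed = 1, n_replicates = 1))
#' run$prediction$summary
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(stage, n) {
    if (!quiet) message(sprintf("[phytocomp] %-22s %6d records", stage, n))
  }
  panel <- if (is.null(config$panel)) {
    default_species_panel(jitter_sd = config$jitter_sd, seed = config$seed)
  } else if (inherits(config$panel, "species_panel")) {
    config$panel
  } else {
    do.call(species_panel, as.list(config$panel))
  }
  designs <- run_designs(config)
  model <- do.call(observation_model, config$observation)

  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  experiment <- with_stage("simulate", generate_experiment(
    panel = panel, n_replicates = config$n_replicates, designs = designs,
    co2_levels = config$co2_levels, noise = config$noise, model = model,
    seed = config$seed))
  say("simulate", nrow(experiment$data))

  growth_fits <- with_stage("growth", fit_growth_rates(
    experiment, method = config$growth_method))
  say("growth", nrow(growth_fits))

  growth_resp <- with_stage("growth_responses", growth_responses(growth_fits))
  say("growth_responses", nrow(growth_resp))

  coeffs <- with_stage("compete", competition_coefficients(
    experiment, growth_fits, r_community = config$r_community,
    freq_floor = config$freq_floor))
  say("compete", nrow(coeffs))

  responses <- with_stage("responses", competition_responses(coeffs))
  say("responses", nrow(responses))

  prediction <- with_stage("predict", prediction_fits(responses, growth_resp))
  say("predict", nrow(prediction$summary))

  # ground-truth parameter recovery for every simulated growth parameter
  est <- growth_fits |>
    dplyr::group_by(.data$species, .data$regime, .data$co2) |>
    dplyr::summarise(r = mean(.data$r), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "co2", values_from = "r",
                       names_prefix = "r_est_")
  recovery <- dplyr::inner_join(
    tidyr::crossing(
      dplyr::select(panel, "name", "r_ambient", "delta_r_co2"),
      regime = config$regimes),
    est, by = c(name = "species", "regime")) |>
    dplyr::transmute(
      species = .data$name, .data$regime,
      r_ambient_true = .data$r_ambient,
      r_ambient_est = .data$r_est_ambient,
      r_high_true = .data$r_ambient + .data$delta_r_co2,
      r_high_est = .data$r_est_high,
      delta_r_true = .data$delta_r_co2,
      delta_r_est = .data$r_est_high - .data$r_est_ambient,
      r_ambient_error = .data$r_ambient_est - .data$r_ambient_true,
      r_high_error = .data$r_high_est - .data$r_high_true,
      delta_r_error = .data$delta_r_est - .data$delta_r_true
    )

  manifest <- list(
    package = "phytocomp",
    version = as.character(utils::packageVersion("phytocomp")),
    seed = config$seed,
    n_replicates = config$n_replicates,
    noise = config$noise,
    growth_method = config$growth_method,
    r_community = config$r_community,
    n_cultures = dplyr::n_distinct(experiment$data$culture_id),
    stages = list(
      cultures = nrow(experiment$data),
      growth_fits = nrow(growth_fits),
      growth_responses = nrow(growth_resp),
      coefficients = nrow(coeffs),
      responses = nrow(responses),
      prediction_fits = nrow(prediction$summary)
    )
  )

  run <- structure(
    list(experiment = experiment, growth_fits = growth_fits,
         growth_responses = growth_resp, coefficients = coeffs,
         responses = responses, prediction = prediction,
         recovery = recovery, manifest = manifest, config = config),
    class = "phyto_run"
  )
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

#' Write all tables of a pipeline run
#'
#' @param run a `"phyto_run"` from [run_pipeline()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "phyto_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_phyto_table(run$experiment$data, p("cultures.csv"), "cultures")
  truth <- tibble::as_tibble(run$experiment$truth)
  class(truth) <- class(tibble::tibble())
  write_phyto_table(truth, p("species_truth.csv"), "species_truth")
  write_phyto_table(run$growth_fits, p("growth_fits.csv"), "growth_fits")
  write_phyto_table(run$growth_responses, p("growth_responses.csv"),
                    "growth_responses")
  write_phyto_table(run$coefficients, p("coefficients.csv"), "coefficients")
  write_phyto_table(run$responses, p("responses.csv"), "responses")
  write_phyto_table(run$prediction$summary, p("prediction_summary.csv"),
                    "prediction_summary")
  write_phyto_table(run$prediction$points, p("prediction_points.csv"),
                    "prediction_points")
  write_phyto_table(run$recovery, p("recovery.csv"), "recovery")
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  write_run_config(run$config, p("config.yaml"))
  invisible(dir)
}

#' @export
print.phyto_run <- function(x, ...) {
  cat(sprintf("<phyto_run> seed %d: %d cultures, %d coefficient rows\n",
              x$manifest$seed, x$manifest$n_cultures,
              x$manifest$stages$coefficients))
  cat("prediction fits:\n")
  print(as.data.frame(x$prediction$summary), row.names = FALSE)
  invisible(x)
}
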