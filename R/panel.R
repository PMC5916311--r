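#' Construct a species panel
#'
#' A species panel is the ground-truth parameter table for simulation: one row
#' per species with its taxon, intrinsic exponential growth rate under ambient
#' CO2, the additive growth response to high CO2, and the counting instrument
#' used for its pure cultures.
#'
#' @param name character, species identifiers (unique).
#' @param taxon character, one of `"cyanobacteria"`, `"chlorophyte"`,
#'   `"diatom"`, `"coccolithophore"`.
#' @param r_ambient per-day intrinsic growth rate under ambient CO2 (>= 0).
#' @param delta_r_co2 per-day additive growth-rate shift under high CO2.
#' @param counting_instrument `"flow_cytometer"` or `"hemocytometer"` per
#'   species.
#' @return A [tibble::tibble] of class `"species_panel"`.
#' @seealso [default_species_panel()]
#' @export
species_panel <- function(name, taxon, r_ambient, delta_r_co2,
                          counting_instrument) {
  taxa <- c("cyanobacteria", "chlorophyte", "diatom", "coccolithophore")
  instruments <- c("flow_cytometer", "hemocytometer")
  if (anyDuplicated(name)) stop("species names must be unique", call. = FALSE)
  if (!all(taxon %in% taxa)) {
    stop("`taxon` must be one of: ", paste(taxa, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(r_ambient)) || any(r_ambient < 0)) {
    stop("`r_ambient` must be finite and >= 0 (per day)", call. = FALSE)
  }
  if (any(!is.finite(delta_r_co2))) {
    stop("`delta_r_co2` must be finite (per day)", call. = FALSE)
  }
  if (!all(counting_instrument %in% instruments)) {
    stop("`counting_instrument` must be one of: ",
         paste(instruments, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    name = as.character(name), taxon = taxon,
    r_ambient = as.numeric(r_ambient),
    delta_r_co2 = as.numeric(delta_r_co2),
    counting_instrument = counting_instrument
  )
  class(out) <- c("species_panel", class(out))
  out
}

#' Default seven-species panel
#'
#' The default simulated community: seven marine phytoplankton species from
#' four major taxa -- the cyanobacterium *Synechococcus* sp., the chlorophytes
#' *Dunaliella tertiolecta* and *Prasinococcus capsulatus*, the diatoms
#' *Phaeodactylum tricornutum* and *Thalassiosira weissflogii*, and the
#' coccolithophores *Emiliania huxleyi* and *Coccolithus pelagicus*.
#'
#' CO2 growth responses are set so taxon means match reported laboratory
#' values: chlorophytes +0.20/day (largest), *Synechococcus* +0.06/day
#' (smallest), diatoms +0.12/day and coccolithophores +0.10/day in between
#' (overall mean 0.129/day). Ambient rates (0.45-0.85/day) are ordered by
#' carbon-concentration-mechanism efficiency: cyanobacteria, with the most
#' efficient CCM, are least CO2-limited today (fast at ambient, small CO2
#' gain); chlorophytes are most CO2-limited (slower at ambient, largest
#' gain). All rates are per day; pure cyanobacteria are counted by
#' hemocytometer (they are not resolved by the flow-cytometry template), all
#' other pure cultures by flow cytometer; mixtures are always counted by
#' microscopy.
#'
#' @param jitter_sd optional standard deviation (per day) of normal
#'   species-level jitter added to `delta_r_co2`, for sensitivity experiments.
#'   Default 0 (the fixed panel above).
#' @param seed integer seed used only when `jitter_sd > 0`.
#' @return A `"species_panel"` tibble with 7 rows.
#' @examples
#' default_species_panel()
#' @export
default_species_panel <- function(jitter_sd = 0, seed = 1L) {
  panel <- species_panel(
    name = c("Synechococcus sp.", "Dunaliella tertiolecta",
             "Prasinococcus capsulatus", "Phaeodactylum tricornutum",
             "Thalassiosira weissflogii", "Emiliania huxleyi",
             "Coccolithus pelagicus"),
    taxon = c("cyanobacteria", "chlorophyte", "chlorophyte", "diatom",
              "diatom", "coccolithophore", "coccolithophore"),
    r_ambient = c(0.85, 0.45, 0.50, 0.65, 0.70, 0.55, 0.60),
    delta_r_co2 = c(0.06, 0.22, 0.18, 0.14, 0.10, 0.12, 0.08),
    counting_instrument = c("hemocytometer", rep("flow_cytometer", 6))
  )
  if (jitter_sd > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(as.integer(seed))
    panel$delta_r_co2 <- panel$delta_r_co2 + rnorm(nrow(panel), 0, jitter_sd)
  }
  panel
}

#' Culture experiment design
#'
#' Describes one culture regime of the standard growth/competition assay:
#' 8 ml cultures inoculated at 1e5 cells/ml per species, sampled daily over a
#' 5-day window. In the semicontinuous regime 1 ml of the 8 ml culture is
#' replaced daily with fresh medium (a 1:8 dilution) immediately after each
#' daily sample from day 1 onward; batch cultures are closed.
#'
#' @param regime `"batch"` or `"semicontinuous"`.
#' @param volume_ml culture volume in ml (default 8).
#' @param duration_days assay length in days (default 5).
#' @param sampling_days sampling times in days, strictly increasing, starting
#'   at inoculation (default `0:5`).
#' @param initial_density starting density per species, cells/ml (default 1e5).
#' @param dilution daily replacement fraction for the semicontinuous regime
#'   (default 1/8; forced to 0 for batch). Must satisfy `0 <= dilution < 1`.
#' @return A list of class `"culture_design"`.
#' @examples
#' culture_design("semicontinuous")
#' @export
culture_design <- function(regime = c("batch", "semicontinuous"),
                           volume_ml = 8, duration_days = 5,
                           sampling_days = 0:duration_days,
                           initial_density = 1e5,
                           dilution = if (regime[1] == "semicontinuous") 1 / 8 else 0) {
  regime <- match.arg(regime)
  if (regime == "batch") dilution <- 0
  if (!is.numeric(dilution) || dilution < 0 || dilution >= 1) {
    stop("`dilution` must satisfy 0 <= dilution < 1", call. = FALSE)
  }
  if (length(sampling_days) < 2 || any(diff(sampling_days) <= 0) ||
      sampling_days[1] != 0) {
    stop("`sampling_days` must be strictly increasing and start at 0 ",
         "(inoculation)", call. = FALSE)
  }
  if (initial_density <= 0) {
    stop("`initial_density` must be positive (cells/ml)", call. = FALSE)
  }
  structure(
    list(regime = regime, volume_ml = volume_ml,
         duration_days = duration_days,
         sampling_days = as.numeric(sampling_days),
         initial_density = initial_density, dilution = dilution),
    class = "culture_design"
  )
}

#' Dilution events implied by a culture design
#'
#' For semicontinuous designs, one event per day from day 1 to the day before
#' the end of the assay, each replacing fraction `dilution` of the culture
#' immediately after that day's sample. Batch designs have no events.
#'
#' @param design a [culture_design()].
#' @return A tibble with columns `day` and `fraction` (possibly 0 rows).
#' @export
dilution_events <- function(design) {
  stopifnot(inherits(design, "culture_design"))
  if (design$dilution == 0) {
    return(tibble::tibble(day = numeric(0), fraction = numeric(0)))
  }
  tibble::tibble(
    day = seq_len(design$duration_days - 1),
    fraction = design$dilution
  )
}

#' @export
print.culture_design <- function(x, ...) {
  cat(sprintf("<culture_design> %s, %g ml, %g days, start %g cells/ml\n",
              x$regime, x$volume_ml, x$duration_days, x$initial_density))
  cat(sprintf("  sampling days: %s; daily dilution: %s\n",
              paste(x$sampling_days, collapse = ", "),
              if (x$dilution > 0) sprintf("%.4g", x$dilution) else "none"))
  invisible(x)
}

# RNG state helpers: save/restore .Random.seed so seeded helpers do not
# disturb the caller's stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

# Deterministic per-culture seed: combine the experiment seed with a stable
# string hash of the culture id, so any subset of cultures reproduces
# identically. Kept below 2^31 - 1.
split_seed <- function(base_seed, key) {
  m <- 2147483647
  h <- 0
  for (cp in utf8ToInt(as.character(key))) h <- (h * 131 + cp) %% m
  as.integer((as.numeric(base_seed) * 48271 + h) %% m)
}
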