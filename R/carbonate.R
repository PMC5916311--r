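#' Seawater carbonate-system equilibrium constants
#'
#' Evaluates a single, named set of published formulations at the given
#' temperature and salinity:
#'
#' * `K0` -- CO2 solubility, Weiss (1974), mol kg-1 atm-1
#' * `K1`, `K2` -- carbonic acid dissociation, Lueker, Dickson & Keeling
#'   (2000), total pH scale, mol kg-1
#' * `KB` -- boric acid, Dickson (1990), total scale, mol kg-1
#' * `KW` -- water, Millero (1995, DOE handbook form), mol2 kg-2
#' * `total_borate` -- Uppstrom (1974), linear in salinity, umol kg-1
#'
#' All concentrations are per kilogram of seawater. The total pH scale is used
#' throughout the package; see [carb_from_ph_ta()].
#'
#' @param temperature_C temperature in degrees Celsius, in `[0, 40]`.
#' @param salinity practical salinity (dimensionless), in `[5, 45]`.
#' @return A list of class `"carb_constants"` with elements `K0`, `K1`, `K2`,
#'   `KB`, `KW` (mol-based units above), `total_borate` (umol/kg),
#'   `temperature_C` and `salinity`.
#' @references
#' Weiss, R. F. (1974) Marine Chemistry 2, 203-215.
#' Lueker, T. J., Dickson, A. G. & Keeling, C. D. (2000) Marine Chemistry 70,
#' 105-119. Dickson, A. G. (1990) Deep-Sea Research 37, 755-766.
#' Millero, F. J. (1995) Geochimica et Cosmochimica Acta 59, 661-677.
#' Uppstrom, L. R. (1974) Deep-Sea Research 21, 161-162.
#' @examples
#' carb_constants(15, 35)
#' @export
carb_constants <- function(temperature_C, salinity) {
  if (!is.numeric(temperature_C) || any(!is.finite(temperature_C)) ||
      any(temperature_C < 0) || any(temperature_C > 40)) {
    stop("`temperature_C` must be finite and within [0, 40] degrees C",
         call. = FALSE)
  }
  if (!is.numeric(salinity) || any(!is.finite(salinity)) ||
      any(salinity < 5) || any(salinity > 45)) {
    stop("`salinity` must be finite and within [5, 45]", call. = FALSE)
  }
  TK <- temperature_C + 273.15
  S <- salinity

  # Weiss (1974), CO2 solubility in mol kg-1 atm-1
  lnK0 <- -60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
    S * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2)

  # Lueker et al. (2000), total scale
  pK1 <- 3633.86 / TK - 61.2172 + 9.67770 * log(TK) -
    0.011555 * S + 0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.9290 - 3.16967 * log(TK) -
    0.01781 * S + 0.0001122 * S^2

  # Dickson (1990), boric acid, total scale
  sqS <- sqrt(S)
  lnKB <- (-8966.90 - 2890.53 * sqS - 77.942 * S + 1.728 * S^1.5 -
             0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqS + 1.62142 * S +
    (-24.4344 - 25.085 * sqS - 0.2474 * S) * log(TK) +
    0.053105 * sqS * TK

  # Millero (1995) / DOE handbook, water dissociation
  lnKW <- 148.96502 - 13847.26 / TK - 23.6521 * log(TK) +
    (118.67 / TK - 5.977 + 1.0495 * log(TK)) * sqS - 0.01615 * S

  # Uppstrom (1974): total boron scales linearly with salinity
  total_borate <- 0.0004157 * S / 35 * 1e6  # umol/kg

  structure(
    list(
      K0 = exp(lnK0), K1 = 10^(-pK1), K2 = 10^(-pK2),
      KB = exp(lnKB), KW = exp(lnKW), total_borate = total_borate,
      temperature_C = temperature_C, salinity = salinity
    ),
    class = "carb_constants"
  )
}

# Total alkalinity (mol/kg) implied by [H+] and CO2(aq), carbonate + borate +
# water terms only.
ta_from_h_co2 <- function(h, co2, k) {
  bt <- k$total_borate * 1e-6
  hco3 <- co2 * k$K1 / h
  co3 <- hco3 * k$K2 / h
  hco3 + 2 * co3 + bt * k$KB / (k$KB + h) + k$KW / h - h
}

carb_state <- function(pH, dic, co2, pco2_uatm, ta_umol, k) {
  tibble::tibble(
    temperature_C = k$temperature_C,
    salinity = k$salinity,
    total_alkalinity = ta_umol,
    pH = pH,
    DIC = dic * 1e6,
    pCO2 = pco2_uatm,
    co2_aq = co2 * 1e6
  )
}

check_ph_ta <- function(pH, total_alkalinity) {
  if (!is.numeric(pH) || any(!is.finite(pH)) || any(pH < 2) || any(pH > 12)) {
    stop("`pH` must be finite and within [2, 12] (total scale)", call. = FALSE)
  }
  if (!is.numeric(total_alkalinity) || any(!is.finite(total_alkalinity)) ||
      any(total_alkalinity <= 0)) {
    stop("`total_alkalinity` must be positive (umol/kg)", call. = FALSE)
  }
}

#' Solve the CO2 system from pH and total alkalinity
#'
#' Completes the seawater CO2 system from the measured pair used in culture
#' monitoring: total-scale pH and total alkalinity. Alkalinity is decomposed
#' as `TA = [HCO3-] + 2[CO3--] + [B(OH)4-] + [OH-] - [H+]` (carbonate,
#' borate and water terms; nutrient terms are not modelled). Given pH, the
#' borate and water terms follow directly, the remainder is carbonate
#' alkalinity, and DIC, CO2(aq) and pCO2 follow algebraically.
#'
#' @param pH total-scale pH, in `[2, 12]`.
#' @param total_alkalinity total alkalinity in umol/kg-seawater (> 0).
#' @inheritParams carb_constants
#' @return A one-row (or `n`-row, inputs recycle) [tibble::tibble] with columns
#'   `temperature_C`, `salinity`, `total_alkalinity` (umol/kg), `pH`, `DIC`
#'   (umol/kg), `pCO2` (uatm) and `co2_aq` (umol/kg).
#' @examples
#' carb_from_ph_ta(8.10, 2300, 15, 35)
#' @seealso [carb_from_pco2_ta()], [co2_drawdown()], [solve_carbonate_table()]
#' @export
carb_from_ph_ta <- function(pH, total_alkalinity, temperature_C, salinity) {
  check_ph_ta(pH, total_alkalinity)
  k <- carb_constants(temperature_C, salinity)
  n <- max(length(pH), length(total_alkalinity))
  pH <- rep_len(pH, n)
  ta <- rep_len(total_alkalinity, n) * 1e-6
  h <- 10^(-pH)
  bt <- k$total_borate * 1e-6
  # carbonate alkalinity once borate and water contributions are removed
  ca <- ta - bt * k$KB / (k$KB + h) - k$KW / h + h
  if (any(ca <= 0)) {
    stop("alkalinity is inconsistent with pH: no physical solution ",
         "(carbonate alkalinity <= 0)", call. = FALSE)
  }
  hco3 <- ca / (1 + 2 * k$K2 / h)
  co3 <- hco3 * k$K2 / h
  co2 <- hco3 * h / k$K1
  dic <- co2 + hco3 + co3
  carb_state(pH, dic, co2, co2 / k$K0 * 1e6, ta * 1e6, k)
}

#' Solve the CO2 system from pCO2 and total alkalinity
#'
#' Completes the CO2 system for water equilibrated with an atmosphere of known
#' pCO2 (e.g. growth-chamber media at ambient ~500 uatm or future ~1,000
#' uatm). CO2(aq) is fixed by Henry's law (`co2 = K0 * pCO2`) and pH is found
#' by root-finding on the total-alkalinity balance (see [carb_from_ph_ta()]),
#' converged to |delta pH| < 1e-9.
#'
#' @param pCO2 partial pressure of CO2 in uatm (> 0).
#' @inheritParams carb_from_ph_ta
#' @return As [carb_from_ph_ta()].
#' @examples
#' carb_from_pco2_ta(1000, 2300, 15, 35)
#' @export
carb_from_pco2_ta <- function(pCO2, total_alkalinity, temperature_C, salinity) {
  if (!is.numeric(pCO2) || any(!is.finite(pCO2)) || any(pCO2 <= 0)) {
    stop("`pCO2` must be positive (uatm)", call. = FALSE)
  }
  if (!is.numeric(total_alkalinity) || any(!is.finite(total_alkalinity)) ||
      any(total_alkalinity <= 0)) {
    stop("`total_alkalinity` must be positive (umol/kg)", call. = FALSE)
  }
  k <- carb_constants(temperature_C, salinity)
  n <- max(length(pCO2), length(total_alkalinity))
  pCO2 <- rep_len(pCO2, n)
  ta <- rep_len(total_alkalinity, n) * 1e-6

  ph <- vapply(seq_len(n), function(i) {
    co2 <- k$K0 * pCO2[i] * 1e-6
    f <- function(p) ta_from_h_co2(10^(-p), co2, k) - ta[i]
    lo <- f(2); hi <- f(12)
    if (is.na(lo) || is.na(hi) || lo * hi > 0) {
      stop("no pH in [2, 12] balances TA = ", ta[i] * 1e6,
           " umol/kg at pCO2 = ", pCO2[i], " uatm (f(2) = ", signif(lo, 4),
           ", f(12) = ", signif(hi, 4), ")", call. = FALSE)
    }
    stats::uniroot(f, c(2, 12), tol = 1e-10, maxiter = 200)$root
  }, numeric(1))

  out <- carb_from_ph_ta(ph, ta * 1e6, temperature_C, salinity)
  out
}

#' CO2 drawdown of a culture relative to blank medium
#'
#' Growing cultures consume dissolved CO2; the drawdown is quantified as the
#' blank-medium pCO2 minus the culture pCO2 at the same temperature and
#' salinity (positive = net uptake by the culture; a culture above the blank
#' yields a negative value, e.g. net respiration or calcification effects).
#'
#' @param culture_state,blank_state one-row carbonate-state tables as returned
#'   by [carb_from_ph_ta()] or [carb_from_pco2_ta()].
#' @return Drawdown in uatm (a single number).
#' @examples
#' blank <- carb_from_pco2_ta(711.2, 2300, 15, 35)
#' culture <- carb_from_pco2_ta(570.8, 2300, 15, 35)
#' co2_drawdown(culture, blank)
#' @export
co2_drawdown <- function(culture_state, blank_state) {
  need <- c("temperature_C", "salinity", "pCO2")
  for (nm in need) {
    if (!nm %in% names(culture_state) || !nm %in% names(blank_state)) {
      stop("carbonate states must have column `", nm, "`", call. = FALSE)
    }
  }
  if (nrow(culture_state) != 1L || nrow(blank_state) != 1L) {
    stop("`co2_drawdown()` compares exactly one culture and one blank state",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(culture_state$temperature_C,
                        blank_state$temperature_C)) ||
      !isTRUE(all.equal(culture_state$salinity, blank_state$salinity))) {
    stop("culture and blank states differ in temperature or salinity",
         call. = FALSE)
  }
  blank_state$pCO2 - culture_state$pCO2
}

#' Solve the CO2 system for a table of samples
#'
#' Tidy-table front end to [carb_from_ph_ta()]: one row per water sample with
#' columns `sample_id`, `ph`, `ta_umol_kg`, `temp_c`, `salinity`.
#'
#' @param samples data frame with the columns above.
#' @return Input columns plus `dic_umol_kg`, `pco2_uatm`, `co2_aq_umol_kg`.
#' @export
solve_carbonate_table <- function(samples) {
  need <- c("sample_id", "ph", "ta_umol_kg", "temp_c", "salinity")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("`samples` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  res <- lapply(seq_len(nrow(samples)), function(i) {
    carb_from_ph_ta(samples$ph[i], samples$ta_umol_kg[i],
                    samples$temp_c[i], samples$salinity[i])
  })
  res <- dplyr::bind_rows(res)
  dplyr::bind_cols(
    tibble::as_tibble(samples),
    tibble::tibble(
      dic_umol_kg = res$DIC,
      pco2_uatm = res$pCO2,
      co2_aq_umol_kg = res$co2_aq
    )
  )
}

#' @export
print.carb_constants <- function(x, ...) {
  cat("Seawater CO2 equilibrium constants (total pH scale)\n")
  cat(sprintf("  T = %g C, S = %g\n", x$temperature_C, x$salinity))
  cat(sprintf("  K0 = %.6e mol/(kg atm)\n", x$K0))
  cat(sprintf("  K1 = %.6e, K2 = %.6e mol/kg\n", x$K1, x$K2))
  cat(sprintf("  KB = %.6e mol/kg, KW = %.6e mol2/kg2\n", x$KB, x$KW))
  cat(sprintf("  total borate = %.1f umol/kg\n", x$total_borate))
  invisible(x)
}
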