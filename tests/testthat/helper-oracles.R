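# Independent oracles, deliberately coded separately from the package
# internals (no calls into phytocomp's solver).

# -- carbonate constants: the same published polynomials, re-evaluated --------
oracle_constants <- function(temp_c, sal) {
  TK <- temp_c + 273.15
  K0 <- exp(-60.2409 + 9345.17 / TK + 23.3585 * log(TK / 100) +
              sal * (0.023517 - 2.3656e-4 * TK + 4.7036e-7 * TK^2))
  # note: 93.4517*(100/T) = 9345.17/T and the salinity polynomial rewritten
  # in T rather than T/100 -- algebraically identical forms
  K1 <- 10^-(3633.86 / TK - 61.2172 + 9.6777 * log(TK) -
               0.011555 * sal + 0.0001152 * sal^2)
  K2 <- 10^-(471.78 / TK + 25.929 - 3.16967 * log(TK) -
               0.01781 * sal + 0.0001122 * sal^2)
  KB <- exp((-8966.9 - 2890.53 * sal^0.5 - 77.942 * sal +
               1.728 * sal^1.5 - 0.0996 * sal^2) / TK +
              148.0248 + 137.1942 * sal^0.5 + 1.62142 * sal -
              (24.4344 + 25.085 * sal^0.5 + 0.2474 * sal) * log(TK) +
              0.053105 * sal^0.5 * TK)
  KW <- exp(148.96502 - 13847.26 / TK - 23.6521 * log(TK) +
              (118.67 / TK - 5.977 + 1.0495 * log(TK)) * sal^0.5 -
              0.01615 * sal)
  BT <- 0.0004157 * sal / 35  # mol/kg
  list(K0 = K0, K1 = K1, K2 = K2, KB = KB, KW = KW, BT = BT)
}

# total alkalinity (mol/kg) from DIC and [H+], carbonate + borate + water
oracle_ta <- function(dic, h, k) {
  denom <- 1 + k$K1 / h + k$K1 * k$K2 / h^2
  co2 <- dic / denom
  hco3 <- co2 * k$K1 / h
  co3 <- hco3 * k$K2 / h
  hco3 + 2 * co3 + k$BT * k$KB / (k$KB + h) + k$KW / h - h
}

# brute-force: bisect over DIC until the alkalinity expression matches,
# then read off pCO2 (uatm)
oracle_pco2_from_ph_ta <- function(ph, ta_umol, temp_c, sal) {
  k <- oracle_constants(temp_c, sal)
  h <- 10^(-ph)
  ta <- ta_umol * 1e-6
  lo <- 0; hi <- 0.1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (oracle_ta(mid, h, k) < ta) lo <- mid else hi <- mid
  }
  dic <- (lo + hi) / 2
  co2 <- dic / (1 + k$K1 / h + k$K1 * k$K2 / h^2)
  co2 / k$K0 * 1e6
}

# bisect over pH on the alkalinity balance at fixed CO2(aq) = K0 * pCO2
oracle_ph_from_pco2_ta <- function(pco2_uatm, ta_umol, temp_c, sal) {
  k <- oracle_constants(temp_c, sal)
  co2 <- k$K0 * pco2_uatm * 1e-6
  ta <- ta_umol * 1e-6
  bal <- function(ph) {
    h <- 10^(-ph)
    hco3 <- co2 * k$K1 / h
    co3 <- hco3 * k$K2 / h
    hco3 + 2 * co3 + k$BT * k$KB / (k$KB + h) + k$KW / h - h - ta
  }
  lo <- 2; hi <- 12
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (bal(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# -- small simulation fixtures -------------------------------------------------
one_species_panel <- function(r = 0.3, dr = 0,
                              instrument = "flow_cytometer",
                              name = "Testus unicus") {
  species_panel(name = name, taxon = "diatom", r_ambient = r,
                delta_r_co2 = dr, counting_instrument = instrument)
}

two_species_panel <- function(r1 = 0.5, r2 = 0.3, dr1 = 0, dr2 = 0) {
  species_panel(
    name = c("Testus primus", "Testus secundus"),
    taxon = c("diatom", "chlorophyte"),
    r_ambient = c(r1, r2), delta_r_co2 = c(dr1, dr2),
    counting_instrument = c("flow_cytometer", "flow_cytometer")
  )
}
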