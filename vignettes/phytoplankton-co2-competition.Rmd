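---
title: "Growth, competition and CO2: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth, competition and CO2: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytocomp)
```

# The question

Major phytoplankton taxa differ in how efficiently they concentrate and use
inorganic carbon. Cyanobacteria run highly efficient carbon-concentration
mechanisms (CCMs) and are barely CO2-limited at today's concentrations;
chlorophytes are among the most CO2-limited groups. As atmospheric CO2 rises,
these physiological differences should translate into predictable shifts in
competitive ability and hence in community composition: taxa that gain the
most growth from extra CO2 should also gain the most ground on their
competitors.

`phytocomp` implements the analysis chain that turns multispecies culture
experiments into that test: per-culture exponential growth rates, predicted
and realized competition coefficients, their CO2 responses, and the
regressions asking whether growth responses predict competitive responses. A
first-class synthetic-data generator reproduces the statistical structure of
the standard experimental design, so the whole chain is testable end to end
without any laboratory data, including full parameter-recovery checks.

# Growth rates

The generative model is density-independent exponential growth over a 5-day
assay window; cultures are assumed to remain in exponential phase throughout
(no carrying capacity is modelled -- a logistic extension would belong in the
simulator, but saturation is deliberately out of scope). The per-day rate
$r$ of a culture is estimated from daily densities $N_t$ (cells/ml) in one of
two ways:

* **endpoint**: $r = \ln(N_T / N_0) / T$;
* **log-linear regression** (default): the OLS slope of $\ln N_t$ on $t$,
  which uses all daily points and returns a standard error.

Which of the two an "exponential growth rate calculated from the log density
ratio over the assay" means is genuinely ambiguous in the field's shorthand,
so both are provided; on noiseless exponential data they coincide exactly
(tested to 1e-9), and the regression is the default because it uses more of
the data.

**Dilution correction.** In the semicontinuous regime a fraction $D = 1/8$ of
the culture is replaced with fresh medium daily, immediately *after* each
day's sample (sample first, then dilute). Each sampled log-density is
therefore raised by $\sum \ln(1/(1-D))$ over the dilution events strictly
before that sample, which restores the uninterrupted exponential trajectory.
Batch and semicontinuous fits of the same underlying rate then agree exactly,
which the tests assert to 1e-9.

Zero or negative densities stop the estimator with an error naming the time
point rather than being silently floored; a configurable density floor is
available for mixture-derived densities where composition counts can hit
zero.

CO2 growth responses are $\Delta r = r_{\mathrm{high}} - r_{\mathrm{ambient}}$
per species and regime, pooling replicate cultures at the response stage only
(never at the fitting stage); growth-chamber assignments are carried as
metadata and chambers are treated as replicates.

# Competition coefficients

Two coefficients quantify competitive advantage of a focal species (1)
against an opponent (2), both dimensionless and antisymmetric in the pair:

* **predicted**, from pure-culture rates only:
  $c_1^p = (r_1 - r_2) / r_{\mathrm{community}}$;
* **realized**, from mixture frequency dynamics:
  $c_1^r = \frac{1}{g_{\mathrm{community}}}
  \ln\!\frac{f_{1,\mathrm{final}} / f_{2,\mathrm{final}}}
            {f_{1,\mathrm{initial}} / f_{2,\mathrm{initial}}}$,

where $f$ are species frequencies at the assay endpoints (day 0 and the final
day by default; a per-interval variant exists but is not the default) and
$g_{\mathrm{community}}$ is the number of community generations. In the full
seven-species community, $f_2$ is the frequency of all other species pooled;
pooling before or after frequency normalization is algebraically identical.

**Generations are doublings.** $g_{\mathrm{community}} =
\log_2(N_{\mathrm{tot,final}} / N_{\mathrm{tot,initial}})$, dilution-corrected,
because "generations" standardly means doublings. This choice has a visible
consequence: in the deterministic (noiseless) limit, with
$r_{\mathrm{community}}$ taken as the realized total-density rate of the
mixture, $c^r = \ln 2 \times c^p$ exactly. Rather than hiding the factor by a
nonstandard log base, the package documents it and tests it (to 1e-9),
and the deterministic realized-vs-predicted regression returns slope
$\ln 2$ and $R^2 = 1$.

**The standardizing rate $r_{\mathrm{community}}$** in $c^p$ is configurable:

* `"mean"` (default): unweighted mean of the pure-culture rates of the
  species in the culture. A *prediction* should use pure-culture information
  only, so it must not borrow mixture data.
* `"density_weighted"`: inoculation-density-weighted mean (identical to
  `"mean"` under the equal-inoculation design).
* `"realized"`: realized total-density growth rate of the matching mixtures,
  the convention under which the $\ln 2$ identity above holds.

**Degenerate frequencies.** A zero (or unit) observed frequency makes $c^r$
undefined. The default is to error; on explicit request a floor of
$\min(1/(2 \times \text{total count}), 10^{-4})$ is applied -- half a count
out of the counted total, capped so that the floor never exceeds a
biologically negligible frequency.

CO2 responses of coefficients are high-minus-ambient differences, pairing
replicates by index across treatments (replicate labels are shared between
chambers). A sign change of the coefficient between treatments is flagged as
a *dominance reversal*; a same-sign change only alters the speed of
competitive exclusion.

# Predictability regressions

For each species and regime, the mean competitive response (over opponents
and replicates at the pairwise level; over replicates at the community level)
is regressed on the species' growth response, by ordinary least squares,
separately per culture regime. The fits report slope, intercept and $R^2$
only: coefficient-level significance testing (ANOVA/MANOVA) is deliberately
out of scope, as those are routine library calls on the emitted tables. A
third regression uses the mean pairwise competitive response to predict the
full-community response.

# The synthetic experiment

`generate_experiment()` emulates the standard design:

* 7 species from 4 taxa (1 cyanobacterium, 2 chlorophytes, 2 diatoms,
  2 coccolithophores);
* 8 ml cultures inoculated at 1e5 cells/ml per species, sampled daily for
  5 days, in exponential growth throughout;
* 2 CO2 treatments (ambient ~506 and high ~1,000 uatm chamber atmospheres)
  x 2 culture regimes (closed batch; semicontinuous with daily 1:8 medium
  replacement);
* per condition and replicate: 7 pure cultures, all 21 unordered pairs, and
  one 7-species community -- 29 cultures; with 12 replicates (2 chamber
  configurations x 2 runs x triplicates) the full design is 1,392 cultures;
* counting noise: flow-cytometry counts are Poisson over an analyzed volume
  (a free parameter, default 0.05 ml, since the per-sample analyzed volume is
  not a published instrument constant) capped at 10,000 recorded events;
  hemocytometer counts are Poisson with the analyzed volume grown so that at
  least 400 cells are expected; mixtures are counted by microscopy as
  multinomial draws of 400 cells over the true frequencies, with the
  mixture's total density counted on the hemocytometer model. The
  cyanobacterium's pure cultures are hemocytometer-counted (it is not
  resolved by the flow-cytometry template); all other pure cultures use the
  flow cytometer.

All randomness flows from one experiment seed: each culture's observation
draw is seeded by combining the experiment seed with a stable hash of the
culture id, so identical seeds give bitwise-identical datasets and any subset
of cultures reproduces on its own.

**Default growth parameters.** CO2 growth responses are set so taxon means
match reported laboratory values -- chlorophytes +0.20/day (largest),
the cyanobacterium +0.06/day (smallest), diatoms +0.12 and coccolithophores
+0.10/day in between (overall mean 0.129/day). Ambient rates span
0.45-0.85/day, comfortably inside the 0.1-3.6 doublings/day range observed in
marine communities, and are *ordered by CCM efficiency*: the cyanobacterium,
least CO2-limited today, grows fastest at ambient CO2 and gains least from
enrichment; the chlorophytes, most CO2-limited, grow slowest at ambient and
gain most. This negative association between ambient rate and CO2 response is
the mechanistic core of the system being emulated, and it is what makes
growth responses predictive of competitive responses; it is a generative
design choice fixed here, not a fitted quantity.

```{r panel}
default_species_panel()
```

**What the simulator does *not* emulate**, and hence what passing tests do
and do not show about real data: no nutrient drawdown or carrying capacity
(real batch cultures eventually saturate), no allelopathy, facilitation or
other direct interactions (realized coefficients in real mixtures integrate
all of these -- here they integrate only growth-rate differences), no chamber
effects, no acclimation dynamics, no plasticity or evolution over the assay.
Recovery of the generating parameters therefore validates the estimators and
the pipeline plumbing, not the biology; agreement between predicted and
realized coefficients is *built into* the noiseless limit and is informative
in the simulation only about noise propagation, not about whether pure
cultures predict mixtures in nature.

# Seawater carbonate chemistry

Culture monitoring measures pH and total alkalinity (TA); the CO2 system is
completed from that pair. The alkalinity expression is
$TA = [\mathrm{HCO_3^-}] + 2[\mathrm{CO_3^{2-}}] + [\mathrm{B(OH)_4^-}] +
[\mathrm{OH^-}] - [\mathrm{H^+}]$ -- carbonate, borate and water terms only.
Nutrient (phosphate/silicate) alkalinity is omitted: the terms are dominated
by carbonate and borate at culture conditions and per-sample nutrient data
are not part of the two-input measurement pair this module serves.

Constants are one named published set, fixed in the tests: Weiss (1974)
CO2 solubility, Lueker et al. (2000) carbonic-acid constants on the **total
pH scale** (used throughout; meter calibrations differ, so the scale is an
explicit, documented convention here), Dickson (1990) boric acid, Millero
(1995) water, Uppstrom (1974) total borate scaling linearly with salinity.
Units: umol/kg-seawater for TA and DIC, uatm for pCO2.

Given pH, the system is algebraic (no iteration); given pCO2 and TA --
needed to simulate media equilibrated with chamber atmospheres -- pH is found
by `stats::uniroot` on the alkalinity balance over pH in [2, 12] with
tolerance 1e-10, and an informative error reports the bracket values if no
root exists. The test suite checks the solver against an independent
brute-force bisection oracle (over DIC for the pH+TA direction, over pH for
the pCO2+TA direction) to 0.1% on pCO2 and 1e-6 on pH, plus monotonicity and
round-trip identities. Full CO2SYS feature parity (multiple pH scales,
fugacity, nutrient alkalinity) is a non-goal, and no attempt is made to match
any particular published absolute pCO2 values, since the alkalinity values,
meter scale and constant set behind them are unreported.

```{r carb}
carb_from_pco2_ta(c(506, 1000), total_alkalinity = 2300,
                  temperature_C = 15, salinity = 35)
```

# Numerical and design choices

* **Seed handling**: helpers that draw random numbers save and restore the
  caller's RNG state; per-culture seeds are `(seed * 48271 + hash(id)) mod
  (2^31 - 1)`, always below 2^31.
* **Table IO**: every table is CSV behind a one-line schema header
  (`# phytocomp-table <name> v1`); reads validate name, version and columns
  strictly. Doubles are written in their shortest round-trip decimal form and
  re-parsed by R's correctly rounded parser, so write/read round trips are
  bit-lossless.
* **Tie-breaks and degenerate inputs**: equal growth rates give coefficient 0
  (a valid value, not an error); a non-growing community makes the predicted
  coefficient undefined (error), as does zero community generations for the
  realized one; zero total density at a time point yields all-zero counts
  flagged `zero_total` rather than an error.
* **Endpoint-method standard error** is reported as 0 (two points carry no
  residual information), so downstream propagation treats endpoint estimates
  as precision-free rather than infinitely precise in disguise.

# Scale of the shipped checks

The package's test suite runs the full factorial design at 12 replicates
(1,392 cultures) across 20 seeds for the parameter-recovery and
predictability properties, 1,000 noisy cultures for estimator bias, and 100
random water samples for the carbonate oracle comparison -- sizes chosen so
the whole suite completes in a few minutes on a single core while keeping
Monte-Carlo error well below the asserted tolerances.

```{r run}
run <- run_pipeline(pipeline_config(seed = 1, n_replicates = 3))
run$prediction$summary
```

# Known limitations

* Exponential-only dynamics: applying the growth-rate estimators to saturating
  real-world series will bias rates low; inspect fits before trusting them.
* The realized coefficient uses endpoint frequencies; with noisy daily counts
  a regression over all days could be more efficient, and the per-interval
  variant is a starting point for that.
* The carbonate module solves only the (pH, TA) and (pCO2, TA) input pairs,
  the two this workflow needs.
* No significance testing is built in; the emitted tidy tables are designed
  to drop straight into `aov()`/`manova()` or mixed models.
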