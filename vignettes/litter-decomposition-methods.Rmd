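---
title: "Methods: microbially explicit litter decomposition, calibration to empirical drivers, and climate projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbially explicit litter decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimicsLitter)
```

# The model

`mimicsLitter` implements a seven-pool, microbially explicit litter and soil
organic matter (SOM) model of the MIMICS family. Carbon flows through two
litter pools (metabolic `lit_m`, structural `lit_s`), two microbial biomass
pools (copiotrophic `mic_r`, oligotrophic `mic_k`) and three SOM pools
(physically protected `som_p`, chemically protected `som_c`, available
`som_a`). All pools are volumetric carbon densities (mgC cm^-3^); kinetics
are hourly.

**Litter inputs.** Annual litterfall (gC m^-2^ yr^-1^) is converted to a
volumetric hourly input using a bulk-soil depth of 10 cm (configurable,
`depth_cm`). Inputs are split between the litter pools by the metabolic
fraction

$$f_{met} = \mathrm{clip}(0.85 - 0.013\,\mathrm{lignin{:}N},\ 0.01,\ 0.99),$$

the field's standard linear litter-quality partition; a fraction
`f_i` (5%) bypasses the litter pools straight into SOM.

**Uptake.** Each microbial group consumes its substrates by reverse
Michaelis–Menten kinetics,
$F = \mathrm{MIC}\cdot V_{max}(T)\,S/(K_m(T)+S)\cdot\theta$, with
$V_{max} = e^{0.063T + 5.47}\cdot 8\times10^{-6}$ and
$K_m = e^{k_s T + 3.19}\cdot 10$ modified per flux channel (`v_mod`,
`k_mod`), a clay-dependent scalar on the available-SOM half-saturation, and
the soil-moisture scalar $\theta\in[0,1]$ multiplying every microbial flux
(uptake of litter, available SOM, and oxidation of chemically protected
SOM). Applying moisture to all microbial fluxes — not only litter
decomposition — is the simplest reading of "a multiplier on decomposition
rate", and is exposed in one place should a narrower scope be wanted.
$V_{max}$ carries a global scaling `vmax_scale = 0.6`, i.e. a 40% reduction
of catabolic capacity, applied to **all** uptake channels (an open design
point: we chose global application because the reduction is described as a
property of the microbes, not of one substrate).

**Assimilation and turnover.** A fraction `cue` of each uptake flux becomes
biomass (0.55/0.25 for the copiotroph on metabolic/structural substrate,
0.75/0.35 for the oligotroph; available SOM uses each group's metabolic
efficiency); the remainder is respired. Microbial turnover is
density-dependent,

$$\mathrm{MICtrn} = \mathrm{MIC}^{\beta}\,\tau\,f_S,\qquad
\tau = \tau_0\,e^{\tau_m f_{met}},$$

with $\beta = 1.5$ by default ($\beta = 1$ recovers linear turnover
exactly), $\tau_0 = 5.2\times10^{-4}, 2.4\times10^{-4}$ h^-1^ and litter
quality coefficients $\tau_m = 0.3, 0.1$ for the two groups. Turnover is
partitioned among the SOM pools by clay- and quality-dependent fractions
$f_S$ that sum to one. Physically protected SOM desorbs to available SOM at
$1.5\times10^{-5} e^{-1.5\,clay}$ h^-1^; chemically protected SOM is
oxidised to available SOM with its half-saturation amplified by `k_o = 6`.
Carbon is conserved identically: input − respiration − d(total)/dt = 0 to
machine precision, and the test suite asserts it to 1e-10 relative over
random states.

Defaults not printed in the main analysis tables follow the canonical
published MIMICS configuration and live in one YAML file
(`inst/extdata/mimics_params.yaml`), so an alternative configuration can be
dropped in verbatim. The four calibratable parameters — the litter-quality
coefficient on copiotrophic turnover, $\beta$, and the metabolic and
structural $V_{max}$ modifiers — are scaled by multipliers bounded by the
published ranges (`multiplierRanges()`).

# Steady states

Site steady states are solved from constant annual-mean forcing (Table of
site statistics shipped in `inst/extdata/site_table.csv`). The solver is a
damped Newton iteration on log-transformed pools (which keeps pools
positive and handles the `MIC^β` non-smoothness at zero), **preceded by a
20-year forward spin-up from a standard initial state** (RK4, 96-hour
step). The spin-up matters: the algebraic system can have spurious
boundary roots in which one microbial group is extinct. With $\beta > 1$
such roots are always invasible — per-capita turnover vanishes as biomass
shrinks while per-capita growth stays positive — so they are not attractors,
but an un-warmed Newton iteration can land on them. Spinning up first pulls
the state onto the attracting branch; Newton then drives the residual below
1e-8 relative to the input flux (the returned `residual_rel`). A 300-year
integration is the fallback if Newton stalls. When $\beta$ approaches 1
(the low end of its multiplier range), competitive exclusion becomes
quasi-stable and the attained branch can depend on the protocol; the fixed
spin-up makes the protocol deterministic, and the same protocol is used
when generating synthetic observations and when evaluating candidate
parameter sets, so comparisons are internally consistent. A microbial pool
below 1e-6 mgC cm^-3^ is flagged non-viable; the floor quantifies
"maintained viable groups" for the calibration filter, which the source
analysis leaves qualitative.

The solver is verified against an independent oracle — `deSolve::lsoda`
integrating the pure-R derivative implementation for 500 years — to within
1% on all 21 calibration-site configurations.

# Litterbag simulations

Litterbags are two overlay pools (metabolic/structural, split by
$f_{met}$ of the bag litter) decomposed by the *fixed* steady-state
microbial pools under a cycled daily climatology; the bag feeds nothing
back, and *all* decomposed carbon — respired and would-be-assimilated alike
— leaves the system (the respired/assimilated split is reported as a
diagnostic). Bags deploy on day-of-year 315 (November 11) and run to the
end of the third calendar year. Mass loss is read at 10 and 21 months using
1 month = 30.42 days (days 304 and 639); percent mass and percent carbon
remaining are treated as equivalent. The initial bag density (0.056
mgC cm^-3^ ≈ 5 g litter at 45% C in a 20×20 cm bag over the 10-cm depth)
is small against the half-saturation constants, so fractional mass loss is
nearly independent of it. Integration is daily RK4; a 10×-refined-step
reference agrees within 0.1% mass remaining.

The historical design enumerates 7 sites × 3 litter types × 3 soil-moisture
variants = 63 runs (the moisture variants multiply the site's moisture
scalar by its min/1/max multipliers, derived from 95% confidence intervals
of field moisture over the mean — `computeMoistureMultipliers()`).

# Microbiome grouping

Taxonomy-labelled ASV count tables (TSV; semicolon-delimited `rank:name`
lineages) are rarefied to 2447 reads per sample without replacement
(samples below depth are dropped and reported), classified
copiotroph/oligotroph by the finest matching rank rule, and summarised as
per-sample ratios of copiotroph over oligotroph read sums, excluding
unassigned reads. The unassigned-taxa sensitivity sweep reallocates the
unassigned reads between the groups in 10% steps; the resulting ratio is
monotone in the copiotroph share. The shipped rule file is a small
demonstration set mirroring the broad memberships the amplicon literature
names (Alphaproteobacteria, Bacteroidetes, Gammaproteobacteria as
copiotrophs; Acidobacteria, Planctomycetes, Verrucomicrobia as oligotrophs);
it does not reproduce any published full criteria list, and users supply
their own rule table for real analyses.

# Effect sizes

Percent mass loss at both timepoints is modelled as a linear mixed model on
three standardized predictors — log-transformed soil moisture, lignin:N,
and the copiotroph:oligotroph ratio — with random intercepts for site and
plot-within-site (REML, `lme4`). Standardization is per analysis table (the
empirical and model-output tables are standardized separately). A singular
plot-level fit falls back to a site-only random intercept, which is common
for model-output tables whose within-plot structure is deterministic.
Coefficients are relativized to signed percentages summing to 100 in
absolute value, over the three fixed effects only (the intercept is
excluded so the absolute sizes total 100). Variance inflation factors use
the closed form $1/(1-R^2_i)$ with a pass mark of 5. For model output,
"plot" is each litter × moisture-variant combination, the moisture
predictor is the temporally averaged scalar of that variant, and the
community predictor is the steady-state `mic_r`:`mic_k` biomass ratio. The
calibration loop refits this model thousands of times on tables whose
grouping never changes, so `makeEffectFitter()` prebuilds the lme4
structure once; it agrees with the reference fit to optimizer tolerance.

# Monte Carlo calibration

`calibrate()` draws multiplier sets independently and uniformly within the
published ranges (the source says only "random"; independent uniform is the
simplest defensible choice and is seeded), evaluates each set through the
full 63-run design, and applies four filters: (1) simulated site-mean mass
loss inside the observed min–max envelope for every site and timepoint,
(2) relative effect sizes within 10 units of the observed ones for all
three drivers, (3) RMSE below 5.4% over site × timepoint means (14 values
for 7 sites — the envelope granularity; the aggregation grain is
configurable because the source does not state it), and (4) viable
copiotrophs *or* oligotrophs in every run. Survivors are ranked by RMSE
(decomposition is matched in preference to effect sizes), ties broken by
summed absolute effect-size deviation; the top three form the calibrated
ensemble. A holdout stability check repeats filtering and selection on 90%
subsets and reports how consistently the retained full-data selections are
re-selected. Failed evaluations (solver non-convergence) are recorded as
failed records, never silently dropped.

**Identifiability.** The four-multiplier design is deliberately
parsimonious, and partly sloppy: the copiotroph-turnover quality multiplier
spans only a ≤ ~30% change in the underlying turnover rate across its whole
range, and compensating combinations of $\beta$ and the $V_{max}$
modifiers reach the observation-noise RMSE floor along a manifold rather
than at a point. In closed-loop experiments (observations generated from a
known multiplier set plus plot-level noise, then recalibrated with 500
draws), the selected sets match the truth's mass loss and effect sizes
closely while the multipliers themselves — especially the turnover
multiplier — scatter widely; demanding all four multipliers within 15% of
the truth succeeds in well under half of seeded repetitions. This
equifinality is a property of the calibration target, not a solver defect,
and is consistent with the spread among the published best-fit sets, whose
turnover multipliers differ by more than a factor of two. Consumers of the
calibrated ensemble should treat it as an ensemble over the sloppy
directions, not as point estimates of microbial traits.

# Climate experiment

Future forcing is historical forcing plus a monthly anomaly (additive for
temperature and the moisture scalar — the latter clipped to [0, 1] with
clipped days flagged — and multiplicative for litterfall; multiplicative
was chosen because litterfall anomalies scale with productivity). When no
real anomaly file is supplied, `syntheticAnomaly()` builds an SSP-like
anomaly ramping linearly from zero in 2022 to its 2072–2074 targets with a
seasonal shape (stronger winter warming, wetter winters/drier summers);
defaults are +3.0 °C annual-mean warming ± 1.0 °C seasonal modulation,
±0.04 seasonal moisture delta, and a 1.10 litterfall multiplier — a
plausible mid-range for a high-emissions scenario at these latitudes over
50 years. Future steady states are re-solved from the anomaly-shifted
annual means before the litterbag overlay, mirroring the historical
protocol (the alternative — keeping the historical background — is not what
"forcing the model with future inputs" implies for a steady-state
protocol).

The response is the per-run change in mass loss (future − historical) for
default and calibrated models; the headline contrast is the percent
difference of the calibrated (ensemble-mean) response against the default,
guarded below 0.1 percentage points of default response where the ratio is
unstable (the absolute difference is reported there, flagged). Drivers of
the 126-row contrast table (7 sites × 2 timepoints × 3 litters × 3
moistures) are analysed with the same mixed-model machinery in three
covariate variants (historical values, future values, or their change).

# Synthetic data

The generators exist so every stage is testable without downloads:

* `generateDailyForcing()` builds 365-day climatologies as seasonal
  sinusoids plus seeded noise, affinely adjusted so the annual mean matches
  the site statistic within 0.5% and the SD within 10%, moisture clipped to
  [0, 1] (with one recentring pass so clipping does not bias the mean), and
  an autumn litterfall pulse normalised to the annual total.
* `generateObservations()` emits 124-row plot-level observation tables
  (7 sites with 5–12 plots each, two timepoints) with the
  stated sign structure — moisture +8, lignin:N −7, copiotroph:oligotroph
  −5 on the standardized scale, site/plot/residual SDs 5/3/5% — values
  chosen once as field-plausible magnitudes producing total variation
  comparable to litterbag studies. The generating truth is attached for
  recovery tests.
* `generateAsvTable()` emits multinomial count tables with known
  copiotroph/oligotroph/unassigned read shares and lineages built from the
  rule set, so classification recovers the labels and the true ratio is
  known.
* `syntheticObservedMassLoss()` runs the model under a reference multiplier
  set (the first published calibrated set) and adds 2% plot-level noise,
  producing the observation side (site means, min–max envelopes, observed
  effect sizes) of a self-consistent calibration demonstration.

What the generators do *not* emulate: multi-year forcing variability (the
climatology is a single cycled year), spatial autocorrelation beyond the
site/plot hierarchy, fungal communities, nitrogen, leaching or
fragmentation. Passing tests therefore demonstrate internal correctness of
the pipeline and recoverability under the assumed structure, not agreement
with any particular field dataset.

# Numerical choices and problem sizes

Tolerances: steady-state residual 1e-8 (relative to input flux); carbon
balance asserted at 1e-10 relative; solver-vs-oracle agreement 1%;
litterbag step error 0.1%. Degenerate inputs: zero litterfall returns the
all-zero steady state; zero-variance predictors and rank-deficient designs
are refused by name; samples under the rarefaction depth are dropped and
reported; undefined ratios (no oligotroph reads) are flagged errors.
Hot paths (derivatives, Newton, litterbag integration) are compiled (Rcpp)
with a pure-R reference implementation cross-checked in the tests.

The test suite runs the calibration recovery at 500 draws × 20 repetitions
and the solver oracle at 21 configurations × 500 years; the shipped
demonstrations use 500-draw calibrations. These sizes were chosen so the
full suite completes on a laptop in well under half an hour while keeping
every check statistically meaningful; the full published-scale calibration
(5000 draws) is one argument away (`calibrate(n = 5000)`).

# Known limitations

* The default kinetic configuration is the canonical published one, not the
  source study's exact supplementary table; headline empirical numbers
  (effect sizes, calibrated multipliers, climate responses) are therefore
  not expected to reproduce, and the package makes no such claim.
* One soil layer, carbon only, bacteria-oriented community representation.
* The calibration is a filter-and-rank scheme; it quantifies neither
  posterior uncertainty nor the sloppy directions it inherits (see
  *Identifiability*).
* The litterbag overlay ignores within-bag succession, mesofauna and
  leaching; decomposition competes with nothing.
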