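---
title: "Quantifying trout adulteration in salmon by duplex ddPCR: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying trout adulteration in salmon by duplex ddPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmoquant)
```

## The measurement model

Droplet digital PCR partitions a 20 µL reaction into roughly 20,000 droplets
of about 0.85 nL. If template molecules land in droplets independently, the
copy count per droplet is Poisson with mean $\lambda$, and the observed
negative fraction estimates $e^{-\lambda}$, so

$$\hat\lambda = -\ln\frac{N - P}{N}, \qquad
  \widehat{\text{copies/µL}} = \hat\lambda / v,$$

with $N$ total droplets, $P$ positive droplets and $v$ the droplet volume in
µL. `estimate_lambda()` and `estimate_concentration()` implement this
inversion. A fully positive well leaves $\lambda$ unbounded; such wells are
either an error or, on request, flagged `saturated` and excluded from
calibration.

The duplex assay reads trout (FAM) and salmon (HEX) myoglobin in the same
well. Myoglobin is a single-copy nuclear gene, so copies per unit meat mass
are species constants $C_O$ (trout) and $C_S$ (salmon), and the meat mass
ratio follows from the measured copy concentrations $Q_O$, $Q_S$ in one step:

$$\frac{M_O}{M_S} = \frac{C_S}{C_O}\cdot\frac{Q_O}{Q_S}
                  = K\,\frac{Q_O}{Q_S},
  \qquad \text{fraction} = 100\,\frac{Kr}{1+Kr},\; r = Q_O/Q_S.$$

$K$ is calibrated from mixtures of known composition
(`estimate_K()`), each level contributing
$K_i = \frac{f_i}{100-f_i}\cdot\frac{Q_S}{Q_O}$ computed from the
replicate-mean concentrations. For this assay pair the calibrated constant is
$K = 0.43$, packaged as `default_k()`; a fresh calibration overrides it.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `droplet_volume_nl` | 0.85 | nL | converts λ to copies/µL; instrument convention, configurable because published tables are in copies/µL and volume-independent |
| `conf_level` | 0.95 | – | Wilson interval level |
| `k` | 0.43 | – | copy-ratio → mass-ratio constant |
| `lod_pct` | 0.2 | % mass | detection threshold and call tolerance |
| `max_abs_deviation` (LOQ) | 25 | % | acceptable-uncertainty criterion (CAC/GL 74-2010) |
| `max_mismatches` | 2 | bases | in-silico PCR primer tolerance |
| `min_droplets` | 10,000 | droplets | wells below are flagged for exclusion |

**Confidence intervals.** The binomial positive fraction $p = P/N$ gets a
Wilson score interval, mapped through the monotone transform
$\lambda = -\ln(1-p)$. The Wilson form was chosen over Wald (degenerate at
$P=0$) and Clopper–Pearson (conservative); a parametric-bootstrap
cross-check in the test suite confirms the endpoints to within 1%, and
simulated coverage sits in the 93–97% band at nominal 95%.

**Qualitative calls.** Mean fractions at or below the LOD are called
`not_detected` (the numeric value is still reported); at or above
$100-\mathrm{LOD}$, `pure_trout`. The LOD default of 0.2% is where detection
becomes stable (100% positive replicates) for this assay.

**LOD/LOQ rules.** The LOD is the lowest tested level with a 100% detection
rate such that all larger tested levels also reach 100%; the LOQ is the
lowest level within ±25% deviation such that all larger levels also pass. The
"all larger levels" clause means a single failing level *below* a passing run
does not block the answer (the published series has a −25.5% excursion at
0.5% that would otherwise mask the 0.8% LOQ), while any failure above it
does. Deviations are computed from unrounded replicate means; reports can
also render two-decimal values, since several published deviations only
reproduce from unrounded means.

## The synthetic-data generator

`generate_study()` emulates the statistical structure the analysis relies
on, not the fluorescence physics:

* **Mass → copies.** A mixture with trout fraction $f$ contributes
  $f/100 \cdot m \cdot c_o$ trout copies and $(1-f/100) \cdot m \cdot c_s$
  salmon copies ($m$ = extracted mass). Defaults $c_o = 100$, $c_s = 43$
  copies/mg give `true_k = 0.43` and, through the `dilution_factor` of
  0.025 copies per µL of reaction per extracted copy, duplex concentrations
  of tens to hundreds of copies/µL (λ ≈ 0.01–0.2) — the occupancy regime of
  the published calibration wells.
* **Shared extraction noise.** One lognormal draw (mean 1, CV 5% by default)
  scales *both* species of a replicate: both channels come from the same
  tube. This is why the ratio $Q_O/Q_S$ is far more precise than either
  margin, and the test suite asserts exactly that.
* **Degradation.** Thermal/freezing damage is modelled as species-symmetric
  copy loss (`degradation_factor`), because treatment was found
  quantification-neutral and symmetric loss reproduces that: the estimated
  fraction is invariant to it, which the tests verify.
* **Partitioning.** Each droplet holds Poisson($\lambda$) copies; positives
  are drawn in one step as
  $\mathrm{Binomial}\!\left(N, (1-e^{-\lambda})(1-\mathrm{fn}) +
  e^{-\lambda}\mathrm{fp}\right)$, exactly the distribution of per-droplet
  simulation but in O(1). The fp/fn rates coarsely model "rain"
  (ambiguous-amplitude droplets); default 0.
* **Seeding.** One seed drives a study; per-well substreams are derived from
  a counter, so a well's counts do not depend on where its sample sits in
  the design.
* **qPCR.** Ct values follow the standard linear model
  $Ct = a\log_{10}(\text{conc}) + b + \mathcal N(0,\sigma)$, with the
  published slopes/intercepts as defaults in examples and four-fold dilution
  series from 50 down to 0.05 ng/µL.

What the generator does **not** emulate: droplet-volume variability,
amplitude thresholds and true rain structure, inhibition, cross-species
primer competition in heavily degraded matrices, and the empirical
non-linearity of extraction yield with mixture composition (real calibration
tables show per-level yields that a linear mass→copy map cannot produce).
Passing simulation tests therefore demonstrate the *statistical correctness*
of the estimators under the stated model, not instrument-level validity on
real food matrices.

## In-silico PCR

Specificity screening scans templates for primer placements under a Hamming
(no-indel) mismatch model with the 3′-terminal base of each primer required
to match exactly — a mismatch there blocks polymerase extension. IUPAC codes
in primers match their expansion sets; `N` in a template matches nothing.
The default tolerance of two mismatches per primer is a deliberate
approximation: experimental specificity panels do not state an equivalent
tolerance, and no thermodynamic model is attempted. Probe presence is
reported per product rather than used as a filter. The packaged templates
(`synthetic_mb_templates()`) are synthetic stand-ins carrying the published
binding sites at the published spacings (93 bp and 141 bp products) for
offline use; they are not the GenBank records.

## Numerical and design notes

* **Rounding modes in calibration.** `estimate_K()` supports `raw`
  (default) and `two_decimals`. The published per-level K column is itself
  rounded to two decimals, and its RSD (3.02%) only reproduces from those
  rounded values; recomputing K from the *printed* concentrations and then
  rounding flips the 10% level from 0.44 to 0.45 because the original column
  was derived from unrounded replicate means. Reports therefore quote the
  raw-mode mean (which rounds to 0.43) and, where the published spread is
  wanted, the RSD of the published column itself.
* **Replicate handling.** K is computed from replicate-mean concentrations
  per mixture level, then averaged across levels — not per-replicate K values
  averaged — matching how calibration tables are constructed.
* **ANOVA.** The treatment-effect test is the classical equal-variance
  one-way F test (`stats::oneway.test`); the degenerate zero-within-variance
  case returns `F = Inf`, `p = 0` with a flag instead of `NaN`.
* **OLS.** Dynamic-range and standard-curve fits use `stats::lm`; tests
  cross-check the coefficients against explicit normal equations at 1e-10.
* **Precision.** Repeatability is the mean within-run RSD per level;
  reproducibility is the RSD of run-cell means per level; both are averaged
  across levels for the summary figures.

## Problem sizes used in tests

Simulation-based checks run at: 50 seeded calibration studies (5 levels × 6
replicates) for K-recovery bias (<3%); 200 wells per λ for estimator
consistency (<1%); 1,000 wells for CI coverage; 2,000 null ANOVA datasets for
the type-I error band [0.03, 0.07]; 20 seeded verification studies for
deviation recovery. These sizes make the Monte-Carlo error comfortably
smaller than each asserted tolerance while keeping the default suite fast.

## Known limitations

* K is assay- and protocol-specific; the packaged 0.43 applies to this
  myoglobin duplex under the calibration's extraction protocol. New
  primer/probe sets or kits need recalibration.
* The one-step formula assumes both targets are single-copy and equally
  amplifiable after processing; heavily processed matrices that degrade the
  longer (141 bp) trout amplicon faster than the 93 bp salmon amplicon would
  bias the ratio — species-asymmetric degradation is exactly what the
  generator's symmetric model excludes.
* The qPCR comparator's relative quantity $P_O = 100\,C_O/(C_O+C_S)$ applies
  no copies-per-mass correction by definition; its systematic bias relative
  to ddPCR is reproduced, not corrected.
* In-silico PCR is a sequence-level screen, not a wet-lab specificity claim.
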