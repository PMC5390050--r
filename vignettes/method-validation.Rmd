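---
title: "Indirect calibration of procyanidin oligomers: models, validation statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect calibration of procyanidin oligomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrfquant)
```

## The measurement model

Procyanidin oligomers (dp2–dp10) lack commercial reference standards, so
they cannot each be calibrated directly in routine use. `rrfquant`
implements the indirect scheme: isolated oligomer standards are used
*once* to establish a relative response factor per dp class,

$$\mathrm{RRF}_{dp} = S_{dp} / S_{epi},$$

the ratio of the dp-class calibration slope to the epicatechin slope
measured on the same day and instrument. Routine quantification then needs
only an epicatechin curve:

$$c = \frac{R}{S_{epi}\,\mathrm{RRF}_{dp}}, \qquad
w = c \cdot \frac{V \cdot D}{m},$$

with $R$ the summed dp-class peak response, $c$ the solution concentration
(µg/mL), $V$ the dissolution volume (mL), $D$ the extra dilution factor and
$m$ the sample mass (mg), giving the content $w$ in mg/g. The monomer
class uses RRF = 1 by definition; because the chromatography does not
resolve (−)-epicatechin from (+)-catechin, monomers are quantified as a
single class and no catechin/epicatechin split is attempted.

Two structural assumptions underlie the scheme, and both are what the
validation statistics probe:

1. **Linearity** of the fluorescence response over the working range, for
   epicatechin and for every oligomer (lack-of-fit test).
2. **Transferability of the RRF**: any sensitivity change common to a day
   or an instrument must affect all analytes proportionally, so that it
   cancels in the slope ratio (between-lab RRF dispersion).

## What the synthetic-data generator emulates

The generator (`sim_config()`, `simulate_calibration()`,
`simulate_sample_batch()`, `simulate_spiking()`, `simulate_stability()`,
`simulate_interlab()`) produces every input the pipeline consumes, with
the statistical structure the analysis assumes:

* **Linear response with per-dp slopes.** The true slope of analyte $a$ is
  `epi_slope × RRF_a`, with the reference RRF ladder
  (`rrf_reference()`) as the default truth.
* **Multiplicative Gaussian noise.** Responses are scaled by
  $(1+\varepsilon)$, $\varepsilon \sim N(0, \text{noise\_cv})$. Precision
  of this kind of method is reported as %RSD, which is scale-relative, so
  proportional noise is the faithful model. Negative responses (practically
  unreachable at realistic CVs) are truncated at zero with a warning.
* **Day and lab effects as log-normal sensitivity multipliers** with unit
  mean, shared by all analytes within a (day, lab). This is precisely the
  structure that makes the RRF the transferable quantity: the common
  multiplier cancels in the slope ratio. The first lab is the reference
  instrument (multiplier fixed at 1), so sample batches — which are
  generated without a lab effect — live on the same detector scale as the
  reference calibration.
* **Gravimetric/volumetric chain.** True contents (mg/g) convert to
  solution concentrations through mass, volume and dilution exactly as the
  quantification model inverts them; with all CVs at zero, generation
  followed by quantification is the identity to machine precision (a
  property the test suite asserts).
* **Optional glass-adsorption loss**, a fraction lost per cm² of contacted
  surface, applicable per analyte. The phenomenon (stepwise loss of
  oligomers upon serial dilution in volumetric flasks) is real, but no
  loss coefficient is established for it, so the default is 0 and the
  coefficient is a free scenario parameter.

Default study conditions mirror the validated method: an 8-level
calibration over 5–100 µg/mL with 3 replicates per level on 3 days;
samples of ~100 mg dissolved to 50 mL; fortification at 100% and 200% of
expected content, 3 replicates per level; stability at 0/48/96/168 h; a
collaborative trial of 3 replicates × 2 days per lab. Default CVs are 2%
proportional response noise, 3% between-day and 5% between-lab sensitivity
dispersion — values of the order a validated HPLC-fluorescence method
actually achieves (repeatability 2–6%, between-lab RSDs ~4–7% for
monomers). The default scenario composition (`default_contents()`) is a
procyanidin-rich apple extract: ~1% monomers, oligomers 40–95 mg/g
peaking near dp4–dp7.

What the generator does **not** emulate: raw chromatograms (the unit of
data is the integrated dp-class response), isomer substructure within a dp
class, detector saturation (operationally handled by dilution), carryover,
matrix interferences, and any absolute noise floor — noise is purely
proportional. A passing simulation study therefore validates the
statistical machinery and the inverse-model arithmetic, not
chromatographic performance on real extracts.

## Calibration decisions

**Zero forcing.** The implemented rule is the standard intercept t-test:
forcing is supported when the free-fit intercept is not distinguishable
from 0 at $\alpha = 0.05$. A simpler magnitude comparison (|b| against the
residual standard error of the fit) is also computed and logged, since
practitioners often quote it, but it is not the decision rule: the t-test
is the statistically defensible formalisation of the same intent —
reducing relative error at the low end of the range. Both the verdict and
the comparison are returned so the decision is auditable. On true
zero-intercept data the rule accepts forcing at the nominal ~95% rate
(property-tested).

**Lack of fit.** With replicated levels, the residual sum of squares
splits into pure error and lack of fit; $F = MS_{lof}/MS_{pe}$ is compared
to the critical F at $\alpha = 0.05$ (no level is prescribed by
convention for this use; 0.05 is the default throughout the package).
With only as many distinct levels as model parameters the test has zero
lack-of-fit degrees of freedom and the function raises an explicit error —
an inapplicable test must never read as a pass.

**LOQ.** `loq()` returns $10\sigma/S$ with $\sigma$ the residual standard
deviation of the calibration fit — the formula's "standard deviation of
the response" is not further specified anywhere authoritative, so the
residual SD is used and recorded per fit. Reporting applies a separate
policy, `clamp_loq()`: the reported LOQ is never below the lowest
calibration level used for the analyte's RRF, because values below the
lowest calibrant are extrapolations. With lowest levels of 5 µg/mL
(monomer, dp2–dp5), 10 (dp6), 25 (dp7–dp9) and 50 (dp10), this reproduces
the reported LOQ ladder even though the theoretical LOQ is far lower.

**Pooled vs mean-of-daily.** Whether per-day curves should be pooled or
averaged for the final response factor is genuinely open. The package
exposes both (`fit_calibrations()` on pooled data vs
`compute_rrf_table()`, which ratios per-day slopes and averages), and uses
mean-of-daily ratios by default, mirroring the "mean of means" convention
for RRFs and keeping the day effect out of the ratio.

**Weighting.** Regression is unweighted, matching standard practice for
these calibrations. Under the generator's proportional-noise model an
unweighted fit is mildly inefficient but unbiased; the RRF, as a ratio of
two such slopes, is insensitive to the choice.

## Validation statistics

**Precision.** One-way random-effects ANOVA with day as the factor:
$s_r^2 = MS_{within}$,
$s_{day}^2 = \max\{0, (MS_{between}-MS_{within})/\bar n\}$ with $\bar n$
the harmonic-mean replicates per day, and $s_{ip}^2 = s_r^2 + s_{day}^2$.
The negative-component truncation is the standard restricted estimator;
when it bites, intermediate precision equals repeatability. Under this
estimator intermediate precision can never be *below* repeatability —
published tables where it is are only consistent with reporting the
between-day component alone, so `precision_anova()` returns both
components (`s_r`, `s_day`) alongside the two RSDs and a truncation flag,
letting either convention be read off.

**Recovery.** Per fortified replicate,
$\mathrm{rec} = 100\,(x_{found} - \bar x_{unspiked})/x_{added}$; the
reported recovery averages over all levels and replicates (the
conservative, level-agnostic convention) and $u_{rec}$ is the sample SD of
the individual recoveries. The single-point variant is the same function
on a one-level subset.

**Bias.** No formula is standard for the control-material component, so
$u_{bias}$ combines the relative deviation of the measured mean from the
reference value with the reference's relative uncertainty in quadrature —
the simplest combination that punishes both disagreement and an uncertain
reference. For a defatted control material the certified value is first
rescaled to the defatted basis (`defatted_reference()`).

**Expanded uncertainty.** `expanded_uncertainty()` evaluates
$U = k\sqrt{u_{rep(RRF)}^2 + u_{il(RRF)}^2 + u_r^2/n_1 + u_{ip}^2/n_2 +
u_{bias}^2 + u_{rec}^2}$ with $k = 2$. All components must be percent
relative standard uncertainties; mixing absolute units is rejected at
validation, since the quadrature is meaningless across unit systems.
Optimistic vs maximal budgets are simply two component sets evaluated
through the same formula; no separate machinery is warranted. $n_1$
(total analyses) and $n_2$ (days) are required inputs — no default could
be defended.

**Stability.** `stability_assess()` reports, per analyte, the change from
0 h to the last timepoint and an acceptance half-width equal to the mean
of all timepoint values times the analyte's intermediate-precision
fraction — the rule that reproduces the published acceptance ranges on
every analyte of the reference study (`stability_reference()`). The
`stable` flag compares |delta| to the half-width but is advisory: a drift
smaller than the method's own between-day noise cannot be distinguished
from no trend, so both numbers are always reported and no formal pass/fail
semantics are attached.

## Inter-laboratory evaluation

`consensus_stats()` uses the arithmetic mean and sample SD (n − 1) — the
convention verified to reproduce the published consensus tables.
`z_scores()` computes $(x-\mu)/\sigma$ against those statistics, with the
2/3 classification bands (satisfactory/doubtful/unsatisfactory); a robust
(median/MAD) variant exists but is off by default, matching the plain
formula actually used in such evaluations.

The control-sample gate (`qc_gate()`) defaults to a **leave-one-out** z at
|z| > 3: each lab is scored against the consensus of the *other* labs.
The plain consensus z is available (`policy = "z"`) but is not the
default, because it suffers masking — in an 8-lab set, a lab displaced by
8 between-lab SDs inflates the pooled SD enough that its own plain z is
only ≈ 2.5 and it would survive a |z| > 3 cut. The deleted z detects
exactly such a lab essentially always (the test suite demands a planted
8σ outlier be caught, and nothing else excluded, in 100/100 seeds).
Exclusion is capped at one round: the consensus is recomputed once on the
retained labs, never iterated to exhaustion.

Published per-analyte z-score tables cannot in general be reconstructed
from published per-lab summaries (per-dp lab values are not printed, and
monomer z arithmetic is not internally consistent between such tables), so
the z-score machinery is verified by its mathematical properties —
$x=\mu \Rightarrow z=0$, $\sum z = 0$, $\mathrm{sd}(z)=1$ — and by the
consensus tables, not by reproducing per-lab z values.

## Numerical and engineering choices

* All tests of published anchors assert at the precision those values are
  printed with; where a statistic recomputed from rounded printed inputs
  can legitimately differ in the last printed digit (an SD computed from
  unrounded lab results; a delta of two rounded timepoints), the assertion
  allows exactly one unit in that digit, never more.
* Exact-line inputs (noise-free simulations, closed-form checks) are
  legitimate here, so the "essentially perfect fit" warning from R's
  summary machinery is muffled at the fit sites.
* Degenerate inputs error early and name the offending field: fewer than
  two distinct calibration levels, zero-variance responses, a single day
  for intermediate precision, zero between-lab dispersion for z-scores,
  a QC gate that would exclude every lab.
* Every generator takes its seed from the config and is byte-identical
  across calls; no global RNG state leaks (seeds are set via
  `withr::local_seed()`).
* CSV I/O is fixed to one dialect (comma-separated, header, UTF-8, "."
  decimals). Decimal commas are rejected with a remediation hint rather
  than silently mis-parsed, and schema violations report column names and
  row numbers.
* Simulation problem sizes in the test suite are chosen to put Monte-Carlo
  error well inside the asserted tolerances while keeping the suite quick:
  RRF recovery uses 40 replicate 3-day × 8-level × 3-rep studies (the
  whole-study replication estimates the Monte-Carlo SE directly, rather
  than leaning on the noisy 2-df within-study SD); variance-component
  recovery uses 50–200 days × 10 replicates; null-rate checks use 400–500
  draws, with acceptance bands set at ~3 binomial SEs around the nominal
  rate.

## Known limitations

* The RRF model assumes day/instrument effects are strictly proportional
  across analytes; wavelength-dependent drift or mobile-phase composition
  changes violate this and are exactly why RRFs are method-specific. The
  package cannot detect such violations from a single lab's data — that is
  what the between-lab RRF dispersion term is for.
* The simulator's noise is purely proportional; near-LOQ behaviour of a
  real detector (absolute noise floor) is not represented, so simulated
  theoretical LOQs are not comparable to instrument LOQs.
* The stability rule ties acceptance to intermediate precision; for an
  analyte with very poor precision the band is correspondingly wide, which
  is a property of the rule, not of the chemistry.
* Below-LOQ results are flagged, retained and excluded from class totals;
  no substitution (LOQ/2 etc.) is offered, as any imputation policy would
  be invisible downstream.
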