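---
title: "Methods: from isotope ratios to iron absorption, and the statistics around a low phytic acid screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from isotope ratios to iron absorption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytofer)
```

This vignette is the package's account of its models: what is assumed, which
parameters matter, how the synthetic generators are calibrated, and where the
numerical edges are.

## The dual stable-isotope erythrocyte-incorporation model

The measurement principle is isotope dilution. A subject's circulating iron
is almost entirely haemoglobin-bound, so

* blood volume is estimated from anthropometry — the default model is the
  65 mL/kg convention for adult women (`per_kg`); a height+weight regression
  (`nadler_female`, 0.3561·h³ + 0.03308·w + 0.1833 L) is registered as an
  alternative and the model name is recorded in run provenance;
* circulating iron (mg) is blood volume × Hb (g/L) × 3.47 mg Fe per g Hb
  (standard haem stoichiometry, overridable in `iron_constants()`).

After labelled meals, the blood pool is a three-component mixture: native
iron at natural isotopic composition, plus two enriched labels. Enriched
labels are never pure — a "57Fe" label still carries 54/56/58 — so both
measured ratios (57/56 and 58/56) depend on both label amounts.
`tracer_amounts()` solves the resulting 2×2 linear balance exactly rather
than treating each label independently. Three modelling choices deserve
comment:

* **Baseline calibration.** The subject's pre-dose measured ratios replace
  the nominal natural-abundance ratios for the native pool. This absorbs
  instrument offsets and small individual deviations; if no baseline is
  available the natural ratios are used and the output is flagged.
* **Native pool fixed.** The tracer in blood is well under 1% of
  circulating iron at meal-study absorption levels, so the native mole pool
  is computed once from circulating iron without iterating for tracer
  displacement. A single fixed-point refinement is available
  (`refine = TRUE`) and changes results only in the second decimal of a
  percent.
* **Negative solutions.** Measurement noise around zero enrichment can
  drive a solved label amount slightly negative. Within −10⁻⁶ relative to
  the native mole pool (the dominant scale of the balance) the amount is
  clipped to zero with a message; anything larger is treated as an
  inconsistent measurement and raises an error. Isotopically
  indistinguishable labels make the balance singular and raise a
  degenerate-design error (condition number guard at 10¹²).

Fractional iron absorption divides the circulating label by 80% of the
dose: the conventional assumption that 80% of absorbed iron is incorporated
into erythrocytes by day 14. Absorption is summarised by geometric means
(absorption is right-skewed and compared on logs); the paired t-test runs on
log values and its back-transformed mean difference equals the ratio of
geometric means, a consistency the tests assert. Zero-variance differences
are reported as an explicit `undefined` flag, never as a silent zero.

Natural abundances default to the IUPAC representative values (54Fe 0.05845,
56Fe 0.91754, 57Fe 0.02119, 58Fe 0.00282); label compositions are required
inputs in real use, with ~96% 57Fe and ~99% 58Fe defaults for simulation.

### Atom percent excess

`atom_percent_excess()` reports the absolute rise of the 57Fe and 58Fe atom
fractions over baseline, in percent, after renormalising the measured ratio
pairs to atom fractions under the (exactly satisfied, when only 57/58 labels
are added) assumption that the 54/56 ratio stays natural. Note that at
meal-study doses the day-20 excess is of the order 10⁻³ atom percent; the
*relative* shift of the ratios is the few-tenths-of-a-percent quantity an
isotope-ratio MS laboratory usually quotes, and it is the relative shift
that governs measurement precision (next section).

## Measurement noise in the simulator

`isotope_sim_config()` parameterises measurement uncertainty as the relative
SD of the **enrichment signal** — the baseline→day-20 shift of each ratio —
not of the raw ratio. The reason is scale: at 3 mg label doses and a ~1.5 g
circulating iron pool, the day-20 ratio shift is only ~0.25% (57Fe) to
~0.7% (58Fe) of the ratio itself. An error expressed relative to the raw
ratio at any realistic-sounding magnitude would therefore either swamp the
signal entirely or be meaninglessly small, and its effect on recovered
absorption would depend on dose and body size. Expressed relative to the
enrichment, the default 0.5% propagates to roughly 0.7% relative error on
recovered absorption, matching the sub-percent precision with which
thermal-ionisation instruments quantify such shifts, and stays interpretable
across dose scales. With noise at zero the simulate→invert round trip is
exact to 10⁻⁹, which the tests assert on every run.

Per-subject true absorption is lognormal around a ferritin-linked mean:
expected absorption in percent is `geo_mean·100 + slope·(ferritin − 25.2)`
with slopes −0.108 (low-phytate meal) and −0.060 (high) % per µg/L — the
regression estimates of absorption on serum ferritin — times
`exp(N(0, 0.30))`. The residual log-SD 0.30 is back-computed from the
reported 2.0–7.4% range at n = 10 after removing the ferritin-linked spread.
Subject covariates are drawn from the study population: weight
N(50.5, 4.2²) kg truncated to the observed 41.7–58.4, Hb N(13.7, 0.8²)
truncated to 12.3–15.0 g/dL, ferritin lognormal with arithmetic mean 25.2
and SD 10.1 µg/L truncated to the observed 11.7–40.7 (truncation keeps the
linear ferritin link from driving expected absorption negative; a floor at
0.05% guards the edge). Doses are 1 mg label iron on each of 3 meals per
meal type, 57Fe on the low-phytate meal.

What the generator deliberately does **not** emulate: instrument drift and
fractionation, hepcidin-mediated day-to-day absorption correlation,
meal-order (period) effects in the crossover, and assay error in Hb or
ferritin. Passing recovery tests therefore demonstrate the correctness of
the calculus and the statistical pipeline, not robustness to every
real-world artefact.

## Meal metrics

The phytate:iron molar ratio uses molar masses 660.04 (phytic acid) and
55.845 (iron) g/mol and is scale-invariant in the shared input unit.
Ferritin standardisation adopts the proportional form
`FIA_ref = FIA_obs · (SF_obs / SF_ref)^e` with `e = 1` (configurable): an
equal shift on the log scale, consistent with the approximately log-linear
inverse relation between ferritin and absorption, anchored at identity when
`SF_obs = SF_ref`. With the study-mean ferritin 25.2 µg/L and reference
15 µg/L this maps 3.7% → 6% and 1.3% → 2% at integer-percent rounding.
The arithmetic mean ferritin is used, as printed in the baseline table.

## Quantitative genetics of the screening

One-way ANOVA with accessions as groups (via `stats::anova(lm(...))`, with
exact within-group sums of squares computed separately so that true
zero-error layouts are flagged `Inf`/`undefined` rather than numerical
noise) feeds the expected-mean-squares estimators
`GV = (MS_geno − MS_error)/r` (floored at 0 with a flag), `EV = MS_error`,
`PV = GV + EV`. Coefficients of variation are `100·√V/mean`; broad-sense
heritability `h² = 100·GV/PV`; genetic advance over mean
`100·k·h²·√PV/mean` with `k = 2.06`, the standardised selection differential
at 5% selection — the conventional reporting intensity, and the value that
reproduces the published derived table from its printed components.
Unbalanced layouts are accepted with a warning using the mean replicate
number.

Recomputing the published derived columns from the printed components
reproduces every GCV/PCV/ECV/h² cell at printed precision. Two GAM cells
(25.0 and 23.9 for the panel seasons) recompute to 24.9 and 23.8: the
original calculation evidently used unrounded grand means. One printed PV
cell differs from GV+EV by 0.1 for the same reason. The tests assert
printed-precision agreement where it holds and one-decimal consistency for
the component identity.

The Shannon–Weaver index bins a quantitative trait into 10 equal-width
classes over the observed range (both configurable) and computes
−Σp·log p on natural logs, bounded by log(10) ≈ 2.30. Published per-trait
values near 6.3 exceed log of any plausible class count, implying a
non-standard normalisation that cannot be reconstructed from the available
description; the implementation keeps the standard definition and makes no
attempt to match those values.

Core-collection evaluation reports MD% (share of traits whose means differ
significantly between collection and panel; Welch two-sample test at
α = 0.05), CR% (mean ratio of panel to collection trait ranges; from the
published 19 trait ranges this recomputes to 99.7%, inside the published
99.3 ± 0.5) and VR% (mean CV ratio). Traits with zero range in the parent
are excluded with a warning. Student–Newman–Keuls post-hoc comparisons are
implemented stepwise on the studentized range (`ptukey`/`qtukey`) with the
standard non-testing rule; the harmonic mean group size is used when groups
are unequal.

## Method agreement

Bland–Altman bias is mean(B−A) with 1.96·SD limits of agreement — the
published "random difference ±100" is read as this half-width, giving
SD ≈ 51 for the two-laboratory generator — plus the correlation of
differences with pair means as the magnitude-dependence check. The
difference direction (B − A) is recorded in the output. At n = 19 the
sampling SD of the bias is 51/√19 ≈ 11.7, so recovery tests assert that the
*mean* recovered bias over 200 replicates is centred on the generating 68
(within ±2.5, about 3 standard errors), not that single replicates land
within any tighter band — no estimator could.

## Problem sizes and numerical choices

The test suite exercises: 1,000 random label/spike configurations for the
forward–inverse round trip (asserted to 10⁻⁹ relative); 100 seeded
10-subject studies at 0.5% enrichment noise (≥95% of subject-level
recoveries within ±15% relative); 200 seeded studies for fold-change
recovery (mean within 10% of the generating 2.85); 200 trials at 275
accessions × 3 replicates for variance-component recovery (median h² in
[95, 99]); and 200 two-lab panels at n = 19. These sizes give stable Monte
Carlo summaries while keeping the default suite in the tens of seconds.

Other numerical choices: isotope fractions validate to a 10⁻⁹ sum
tolerance; heritability is clamped to ≤100 against one-ulp overshoot when
EV = 0; paired log-differences constant to machine precision are flagged
undefined; regression on constant ferritin returns an explicit
undefined-slope flag, and a constant response returns slope 0 with r² = 0.

## Limitations

Per-subject isotope ratios and per-accession raw trait values behind the
published summaries were never deposited, so the headline absorption values
(3.7% vs 1.3%) are reproducible only in distribution — via the seeded
generators — not as point values; the packaged summary tables carry the
printed numbers the desk-scale checks recompute against. The printed
phytate:iron ratios (13.5, 23.1) differ by ~1% from ratios recomputed from
the printed rounded compositions, and the printed fold change 2.9 comes
from unrounded geometric means (3.7/1.3 = 2.85); the acceptance checks
carry tolerances of exactly that size and no more.
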