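---
title: "Quantitative muscle ultrasound diagnostics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative muscle ultrasound diagnostics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musono)
```

## The problem

Muscle thickness measured by B-mode ultrasound falls in myopathies,
polyneuropathies and motor neuron diseases, and fasciculations — brief
spontaneous twitches of muscle fascicles — are visible sonographically and
are characteristic of ALS. `musono` turns that observation into a
quantitative diagnostic procedure with three ingredients: a normative
reference for what "thin" means in a healthy person of a given age and
sex; simple counting rules over a fixed battery of muscles; and standard
diagnostic-accuracy summaries of those rules.

The muscle battery is fixed: eight muscles imaged relaxed (biceps
brachii with the underlying brachialis, FDI, APB, ADM, quadriceps,
tibialis anterior, AHB, EDB) and four of them also imaged at maximal
contraction (biceps, APB, quadriceps, tibialis anterior). Fasciculation
presence is recorded per muscle as a boolean over a 15-second scan
window — roughly, muscles twitching at ≥ 4/min are caught. One side is
examined (the right, unless symptoms dominate on the left); side is
carried as metadata and never adjusted for.

## The normative reference

For each (muscle, state, sex, age-stratum) cell, the cutoff is the 5th
percentile of control thickness. Two estimators are available:

* `EMPIRICAL_QUANTILE` — the type-7 linear-interpolation quantile
  (order-statistic position $p(n-1)+1$). This is the default and the
  convention is fixed deliberately: quantile definitions differ in the
  tails at small $n$, and a reference must be bit-reproducible.
* `GAUSSIAN_PARAMETRIC` — $\bar{x} + z_p\,s$, i.e.
  $\bar{x} - 1.6449\,s$ at the 5th percentile.

"Reduced" is a **strict** comparison: thickness exactly equal to the
cutoff is normal, because the definition is *lower than* the percentile.

Default strata are $[18,40)$, $[40,60)$, $[60,90)$ years per sex —
a common stratification in sonographic normative work that keeps every
cell adequately populated with ~65 controls. Edges are inclusive-low.
Ages outside the configured strata raise an error rather than
extrapolate. Cells with fewer than `min_stratum_n = 8` observations fall
back to the Gaussian form with a warning (a 5th percentile from, say, 5
points is dominated by the sample minimum); a stratum with fewer than 2
controls is an error. The exact stratification and estimator used by any
particular published normative dataset are generally not recoverable, so
reproducing external cutoffs is explicitly not claimed — the machinery
here rebuilds a reference from whatever control cohort it is given.

## Decision rules

All rules count only **observed** muscles: an unmeasured muscle is
excluded from numerator and denominator alike, and a subject with no
usable observation for a rule gets a missing verdict, not a negative one
(SMA patients, for instance, are never graded on big-toe extension).

* Thickness rules: positive when ≥ `min_abnormal_muscles` (default 1)
  muscles are reduced; evaluated separately over the 8-muscle relaxed
  block and the 4-muscle contracted block, never mixed across states.
* Fasciculation rules: positive when ≥ 2 of the 8 muscles fasciculate,
  or (the proximal variant) when ≥ 1 of {biceps, quadriceps} does.
  Presence is a boolean per window; frequency is never computed.
* Differentials: biceps − EDB relaxed thickness (cm; low in proximal-loss
  patterns like myopathy and SMA, high in distal-loss polyneuropathy;
  negative values are legal), and MRC elbow flexion − big toe extension
  as its strength analogue. Both are computed for controls too, and both
  propagate missingness.

## Accuracy evaluation

For a binary rule with sensitivity $Se$ and specificity $Sp$, the ROC
"curve" is the polygon $(0,0) \to (1-Sp, Se) \to (1,1)$ and its area is
exactly $(Se+Sp)/2$. This identity is used for all rule AUCs: applied to
the published rule-level rates pooled by group size it reproduces every
published AUC of the emulated study (0.90 relaxed, 0.87 contracted, 0.75
all-muscle fasciculations, 0.87 proximal fasciculations) to two decimals,
which is the evidence that it is the construction behind those numbers.

Continuous markers use the rank-based estimator (pair counting with ties
worth ½, computed via midranks), which the test suite checks against an
exhaustive pair-counting oracle; and group summaries can be turned into a
binormal AUC $\Phi\!\big((\mu_+-\mu_-)/\sqrt{\sigma_+^2+\sigma_-^2}\big)$
— for the biceps−EDB marker this gives 0.83 for polyneuropathy vs
myopathy from the published summaries. No automatic orientation flipping
is performed: an AUC below 0.5 is reported as-is, because silently
flipping hides a mis-specified marker direction (the published
patients-vs-controls value 0.67 for this marker mixes groups shifted in
opposite directions and is not reproducible from summaries; it is left
out of scope).

Pooled sensitivity is the case-count-weighted mean of per-group
sensitivities (equivalently total positives over total cases).
Percentages are displayed to the nearest integer and AUCs to two
decimals; raw proportions and all counts are retained in every
serialized object. Confidence intervals are out of scope.

## The synthetic cohort generator

`default_config()` encodes the emulated study population: group sizes
65/22/36/91/31 (controls, myopathy, polyneuropathy, ALS, SMA),
demographics (e.g. controls aged 47 ± 16 y, 63% female), every muscle's
thickness mean ± SD in both states (e.g. control relaxed biceps
2.51 ± 0.52 cm; ALS 1.81 ± 0.70 cm), MRC scores per movement, and
clinical scales (ALSFRS-R 30 ± 9 for ALS, HFMSE 21 ± 18 for SMA).

Design choices, and what they imply:

* **Independent truncated normals per muscle.** Only marginal summaries
  are published; the inter-muscle correlation is unknowable from them, so
  independence is the default (a correlated extension would be clearly
  non-source). Thickness is truncated below at 0.05 cm, ages at 18–90 y.
  Consequence: statistics that depend on the joint distribution are *not*
  reproduced — the within-subject biceps−EDB SD, the number of abnormal
  muscles per subject, and the overall-rule specificity (independent
  5%-level tests over 8 muscles give $\approx 1-0.95^8 \approx 34\%$
  false-positive rate before estimation noise, vs 15% in the real
  population where per-muscle flags co-occur and the cutoffs came from an
  external normative source). The published biceps−EDB group summaries
  are therefore carried as data (`default_marker_params()`) for the
  binormal check rather than re-derived.
* **Heavy-truncation groups.** Where the published SD is large relative
  to the mean (e.g. myopathy tibialis anterior 1.08 ± 1.24 cm), the
  truncated draw has a higher mean than the configured parameter. The
  generator targets the *pre-truncation* parameters by design; moment
  recovery is only asserted for groups where truncation is negligible
  (controls: the floor sits > 4.5 SDs below every mean, bias < 0.01 cm).
* **Fasciculation calibration.** Per group, two probabilities (proximal,
  distal) are solved so the simulated *rule-level* rates match the
  published ones: the proximal probability solves
  $1-(1-p)^2 = r_{\text{prox}}$ exactly, the distal one solves
  $P(\text{count} \ge 2) = r_{\text{all8}}$ under the Poisson-binomial
  by root finding. Myopathy's published 0% rates force zero
  probabilities, so its small mean fasciculation count is not reproduced
  — rule rates take priority because the rules are what is evaluated.
* **Recording precision.** Thickness is recorded at 0.001 cm. Clinical
  calipers report 0.01 cm, but at that resolution the tie mass at an
  empirical cutoff reaches ~1.3% per bin for thin muscles (APB,
  SD 0.08 cm), and under the strict below-cutoff rule that biases the
  flagged fraction visibly below the nominal 5%. This was set a priori
  as a numerical choice, not tuned to a test.
* **MRC scores** are drawn independently per movement on the half-point
  grid, clamped to [0, 5]. Real strength grades are strongly correlated
  across movements, so the "all recorded MRC = 5" (normal-strength)
  subset is nearly always empty in simulated cohorts, whereas the real
  population had 17/180 such patients. The `--normal-strength-only`
  pathway is therefore exercised for mechanics (subsetting, warnings,
  control retention), not for rate reproduction. Controls carry no MRC
  scores and are always retained in full as the comparison population of
  the subset report.

**What a green test establishes.** The generator demonstrates that the
pipeline is correct on data with the published marginal structure and
calibrated rule rates; it does not demonstrate reproduction of any
joint-distribution statistic of the real cohort, and the subject-level
results of the source population are not desk-reproducible (its
supplementary layout and external normative cutoffs are unavailable).
Accuracy figures that *are* reproduced exactly — the closed-form AUCs and
differential arithmetic — are computed from published rates and
summaries, and the acceptance script recomputes them from the package's
configuration at run time.

## Degenerate inputs and tie-breaks

* Validation is total: a malformed cohort file yields a structured error
  with row/column coordinates, never a partially loaded table; empty
  cells are missing values, never zeros.
* Contracted thickness below relaxed thickness is physiologically odd but
  observed (probe pressure, effort); it is kept and flagged once per
  table as a consolidated warning.
* A non-positive Gaussian cutoff (possible when SD is huge relative to
  the mean) is floored at 0.001 cm with a warning, since a cutoff must be
  positive for the strict rule to be meaningful.
* `quantile` ties: type 7 interpolates between order statistics, so
  constant samples return the constant.
* Seeds: all generator randomness flows from the single configuration
  seed; identical seeds give byte-identical cohort files.

## Limitations

Echogenicity, elastography and fat distribution are out of scope, as are
between-group hypothesis tests, continuous age-regression (LMS) references,
BMI adjustment, confidence intervals for accuracy measures, and any
left/right or longitudinal modelling. The synthetic cohort is a marginal
emulation, as detailed above.
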