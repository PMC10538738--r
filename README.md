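# musono

Quantitative neuromuscular ultrasound is a painless point-of-care tool:
loss of muscle thickness accompanies a wide spectrum of neuromuscular
diseases, while sonographically visible fasciculations point towards
amyotrophic lateral sclerosis (ALS). `musono` implements the diagnostic
analysis pipeline for this kind of study, for clinical neurophysiologists
and biostatisticians who want the whole chain — normative cutoffs,
decision rules, accuracy evaluation — as tested, reusable code:

- **Normative reference**: per-muscle thickness cutoffs at the 5th
  percentile of healthy controls, stratified by sex and age bin, for eight
  relaxed muscles (biceps, FDI, APB, ADM, quadriceps, tibialis anterior,
  AHB, EDB) and four contracted ones (biceps, APB, quadriceps, tibialis
  anterior). Empirical type-7 quantiles, with a Gaussian
  `mean − 1.6449·sd` fallback for thin strata.
- **Decision rules**: a muscle is *reduced* when its thickness is strictly
  below its stratum cutoff; a subject is rule-positive with ≥ 1 reduced
  muscle (relaxed or contracted block). ALS-oriented fasciculation rules:
  ≥ 2 fasciculating muscles of the 8, or ≥ 1 of the proximal pair
  (biceps, quadriceps), observed in a 15-s scan window. Proximal–distal
  differentials: biceps − EDB thickness (cm) and MRC elbow flexion − big
  toe extension.
- **Accuracy**: per-group sensitivity with counts, control specificity,
  pooled sensitivity, and AUC. For a single binary rule the ROC area is
  the trapezoid identity `AUC = (Se + Sp)/2`; continuous markers use the
  rank-based (Mann–Whitney) estimator
  `AUC = P(X_case > X_ctrl) + ½·P(tie)`, or the binormal closed form
  `Φ((μ₊ − μ₋)/√(σ₊² + σ₋²))` from group summaries.
- **Synthetic cohorts**: a seeded generator reproducing the group-level
  structure of a 245-subject clinic population (65 controls, 22 myopathy,
  36 polyneuropathy, 91 ALS, 31 SMA) from published means ± SDs, so the
  whole pipeline is testable without subject-level data.

## Worked example

```r
library(musono)

co  <- simulate_cohort(default_config(seed = 1))
co
#> <musono_cohort> 245 subjects (CONTROL=65, MYO=22, PNP=36, ALS=91, SMA=31)
#>   provenance: simulated(seed=1)

ref  <- build_reference(co[co$group == "CONTROL", ])   # 5th pct, sex x 3 age bins
prof <- classify_cohort(co, ref)
accuracy_report(co, prof)
#> <musono_report>
#>   n: CONTROL=65, MYO=22, PNP=36, ALS=91, SMA=31
#>   relaxed_positive         Se 100%  Sp 49%  AUC 0.75
#>   contracted_positive      Se 92%  Sp 65%  AUC 0.78
#>   fasc_positive_all8       Se 70%  Sp 74%  AUC 0.72
#>   fasc_positive_proximal   Se 73%  Sp 96%  AUC 0.84

evaluate_rule(prof, "fasc_positive_proximal", "ALS",
              c("CONTROL", "MYO", "PNP", "SMA"))
#> <musono_accuracy> rule fasc_positive_proximal
#>   CONTROL: 1/65 = 2%
#>   MYO: 0/22 = 0%
#>   PNP: 4/36 = 11%
#>   ALS: 66/91 = 73%
#>   SMA: 1/31 = 3%
#>   pooled sensitivity 72.5%, specificity 96.1%
#>   AUC = 0.84 (BINARY_IDENTITY)
```

Reading the output: every simulated patient had at least one reduced
relaxed muscle (sensitivity 100%), but so did half the controls — when the
cutoffs are refit on the same 65 controls, testing 8 muscles at a 5% false
positive rate each makes ≥ 1 false flag per control common (≈ 1 − 0.95⁸
plus small-stratum noise). Restricting fasciculations to the proximal pair
trades a little sensitivity (73%) for high specificity (96%), which is the
rule's point for ALS. The closed-form identities reproduce published
accuracies directly from rates:

```r
auc_binary(pool_sensitivity(c(1, 0.92, 0.93, 1), c(22, 36, 91, 31)), 0.85)
#> [1] 0.8993056   # the relaxed-rule AUC, 0.90 at two decimals
auc_binormal(2.06, 0.63, 0.88, 1.07)
#> [1] 0.8290241   # biceps-EDB, polyneuropathy vs myopathy: 0.83
```

## Command line

```sh
Rscript inst/cli/musono simulate  --defaults --seed 1 --out cohort.csv
Rscript inst/cli/musono build-ref --cohort cohort.csv --out ref.json
Rscript inst/cli/musono classify  --cohort cohort.csv --reference ref.json --out profiles.csv
Rscript inst/cli/musono evaluate  --cohort cohort.csv --reference ref.json --out report.json
```

Each command writes a `<out>.manifest.json` (inputs, config digest, seed,
version). Exit codes: 0 success, 1 data/validation error, 2 usage error.
`evaluate --normal-strength-only` restricts patients to those with all
recorded MRC scores equal to 5.

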