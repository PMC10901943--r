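# stainshift

Measuring and improving how well histopathology tile classifiers
transfer between institutions.

A classifier that scores 95 % on held-out tiles from its training
institute can lose ten or more points on slides scanned elsewhere: the
biology is the same, but staining chemistry, scanner color response,
brightness/contrast settings and compression differ. stainshift is a
toolkit for studying and mitigating exactly this, aimed at
computational-pathology researchers who want the *protocol* layer —
color handling, artifact stress-testing, ensemble training plans and
leakage-safe evaluation — independent of any particular deep-learning
framework.

It provides:

* **Stain normalization** (`estimate_stain_profile()`,
  `normalize_to_reference()`): Beer–Lambert optical-density conversion
  (`OD = log10(I0/I)`), sparse nonnegative two-stain factorization
  `OD ≈ W·c` with unit-norm hematoxylin/eosin vectors, and Vahadane-style
  re-rendering of a tile's concentrations through a reference stain
  matrix with 99th-percentile concentration rescaling.
* **HSV color augmentation** (`hsv_augment()`), applied to training
  tiles only.
* **Artifact injectors** (`apply_artifact()`): Gaussian blur (σ in px),
  JPEG round-trips at a given quality, brightness offsets and linear
  contrast about mid-gray — each an exact identity at neutral strength,
  plus strength sweeps and a PSNR probe.
* **Patient-stratified cohorts** (`load_manifest()`,
  `patient_stratified_split()`, `sample_tiles_per_case()`): tibble-based
  tile records; no patient ever crosses a split boundary.
* **Bagging and NoisyEnsemble plans** (`make_ensemble_plan()`): per
  member, a patient subset plus single-class-per-patient label flips
  targeting 15 % of training labels, flipped group-by-group and fully
  auditable (JSON serialization of every flip).
* **An evaluation harness** (`run_normalization_experiment()`,
  `run_artifact_experiment()`, `run_ensemble_experiment()`): paired-seed
  internal-vs-external accuracy, the artifact performance gain
  Δ = accuracy(+artifact) − accuracy(−artifact), robustness curves, and
  exact sign tests; results come with `tidy()`, `glance()` and
  `autoplot()` methods.
* **A synthetic H&E-like generator** (`generate_cohort()`) in which
  class signal is purely morphological (nucleus density) and domain
  signal is purely colorimetric (stain matrix, brightness, contrast), so
  every claim above is testable at desk scale; and a small deterministic
  **reference classifier** satisfying the pluggable
  `fit()`/`predict_proba()` contract (`check_classifier_contract()`
  validates any model you wrap).

## Worked example

```r
library(stainshift)
library(dplyr)

# Two virtual institutes: domain A (training site) and domain B, whose
# scanner renders the same tissue with rotated stain vectors,
# brightness +10 and contrast 1.1.
cohort   <- generate_cohort(n_patients = 40, tiles_per_patient_per_class = 8,
                            seed = 11)
internal <- filter(cohort, domain == "A")
external <- filter(cohort, domain == "B")

report <- run_normalization_experiment(internal, external,
                                       n_seeds = 5, seed = 42)
report
#> <normalization_experiment>
#> # A tibble: 6 × 5
#>   mode             dataset  mean_accuracy sd_accuracy n_seeds
#>   <chr>            <chr>            <dbl>       <dbl>   <int>
#> 1 hsv_augmented    external         0.961     0.00568       5
#> 2 hsv_augmented    internal         0.956     0.0356        5
#> 3 raw              external         0.92      0.0254        5
#> 4 raw              internal         0.962     0.0360        5
#> 5 stain_normalized external         0.956     0.00513       5
#> 6 stain_normalized internal         0.962     0.0284        5
```

Read: without color handling the model loses ~4 accuracy points on the
external institute (0.962 → 0.920). Normalizing every tile to a shared
reference recovers almost all of it (0.956) while leaving the internal
test untouched (0.962 in both modes); HSV augmentation of the training
tiles achieves a similar external recovery here. `tidy(report)` gives
the per-seed runs, `autoplot(report)` the summary figure.

The stain estimator itself is a first-class object:

```r
tile <- generate_tile(1, default_domain_styles()$A, seed = 3)
estimate_stain_profile(tile)
#> <stain_profile>
#>   hematoxylin  eosin
#> R      0.5632 0.0801
#> G      0.7814 0.9895
#> B      0.2688 0.1199
#> concentration scale (p99): H = 1.257, E = 0.580
```

and a NoisyEnsemble plan records every subset and flip it prescribes:

```r
plan <- make_ensemble_plan(internal, n_members = 15, seed = 7)
plan
#> <ensemble_plan: 15 members, subset fraction 0.80, target noise 0.15, seed 7>
#> mean realized noise rate: 0.156
```

A thin command-line front end over the same functions ships in
`inst/cli/stainshift.R`
(`simulate` / `normalize` / `corrupt` / `plan-ensemble`), e.g.

```sh
Rscript inst/cli/stainshift.R simulate --patients 20 --out tiles/
Rscript inst/cli/stainshift.R normalize --reference tiles/A_p01_c0_t001.png \
    --manifest tiles/manifest.csv --out normalized/
```

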