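---
title: "Metabolic tumor response classification: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic tumor response classification: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petresp)
```

## The problem

When patients with metastatic, radioactive-iodine-refractory thyroid cancer
are treated with a tyrosine kinase inhibitor such as lenvatinib, an early
FDG-PET/CT follow-up (a few months into therapy) can separate patients who
are benefiting from treatment from those who are progressing.  Several
competing rule systems translate the change in lesion glucose uptake between
a baseline and a follow-up scan into a four-level metabolic response
category — complete metabolic response (CMR), partial metabolic response
(PMR), stable metabolic disease (SMD), progressive metabolic disease (PMD) —
which is then dichotomized into *disease control* (DC = CMR, PMR or SMD)
versus *progressive disease* (PD = PMD) for clinical decision making and
survival comparison.

`petresp` implements four such rule sets on a common engine:

| rule set     | uptake metric | response / progression floor | extra conditions |
|--------------|---------------|------------------------------|------------------|
| PERCIST 1.0  | SULpeak       | ±30%                         | ±0.8 SUL units absolute; size +30%; new lesion |
| mPERCIST     | SUVpeak       | ±30%                         | +0.8 units absolute (PMD only); size +30%; new lesion |
| PERCISTmax   | SUVmax        | ±30%                         | +0.8 units absolute (PMD only); size +30%; new lesion |
| EORTC        | SUVmax        | ±25%                         | longest diameter strictly >+20%; new lesion |

All "at least" thresholds are inclusive; EORTC's diameter rule is strictly
greater-than.  Precedence when rules conflict is PMD > CMR > PMR > SMD: a new
FDG-avid lesion is unconditional progression even if the target lesion shrank.

## Uptake quantification

The quantification layer computes, per lesion and scan:

* **SUV** = activity concentration (kBq/mL) divided by injected activity per
  body weight (kBq/g), via `to_suv()`.
* **SUL** = SUV × normalizer / weight, via `suv_to_sul()`.  The normalizer is
  lean body mass by the Janmahasatian formula by default, with the James
  formula and a Du Bois body-surface-area mass equivalent (BSA scaled by the
  70 kg / 1.73 m² reference adult, so values stay on the SUV scale) as
  alternatives.  The literature describing SULpeak is inconsistent about
  whether the correction is lean-mass- or surface-area-based, so the method
  is a recorded configuration flag and none of the three is asserted as "the"
  definition.
* **SUVpeak** (`suv_peak()`): the maximum, over candidate sphere centers at
  voxel centers inside the lesion mask, of the mean of all grid voxels whose
  centers fall within a 12-mm-diameter (~1 cm³) sphere.  The sphere may
  extend beyond the lesion; voxels outside the grid are excluded from the
  mean.  A voxel belongs to the sphere when its *center* is within the
  radius — no partial-volume weighting.
* **MTV** (`mtv()`): threshold delineation at 42% of the lesion SUVmax
  (configurable, optional absolute floor), grown from the lesion's hottest
  voxel over face-adjacent (6-connected) voxels; MTV is the delineated voxel
  count × voxel volume.  **TLG** = MTV × SUVmean, exactly.
* **Liver reference** (`liver_reference()`): mean and *population* SD
  (divisor *n*) of SUL and SUV over a 3-cm sphere in the right liver lobe.
  The population SD choice is documented because the measurability rule
  below multiplies the SD by 2 and would otherwise be irreproducible.
* **Longest diameter** (`longest_diameter()`): maximum distance between
  voxel centers of the delineation mask (all-pairs, with a boundary-voxel
  reduction for large masks).

## Eligibility screening

Two filters decide whether a rule set can classify a patient at all:

* **Measurability**: a target lesion must have SULpeak ≥ 1.5 × (liver
  SULmean + 2 SD).  The floor is evaluated at baseline on each rule set's own
  metric — SULpeak for PERCIST 1.0, SUVpeak (against the liver SUV
  statistics) for mPERCIST — while PERCISTmax and EORTC only require a
  positive SUVmax.  Patients failing this are *not assessable* (n.a.).
* **Comparability**: the liver reference mean may differ by at most 20%
  between scans; a strictly larger drift makes the pair *not comparable*
  (n.c.).  The rule applies to all three PERCIST variants and not to EORTC,
  matching the exclusion pattern of clinical series in which EORTC could
  classify every patient.  Whether the drift is measured on the liver SUVmean
  or SULmean is a configuration option (`comparability_metric`); the two are
  proportional in the synthetic data, so the default (SUVmean) is also what
  the SUL-based variants use.

`not_comparable` dominates `not_available` when both apply.

## Target selection

With several lesions per patient, two conventions are offered
(`selection = "hottest"` / `"all"`):

* **Hottest**: the PERCIST family compares the hottest lesion of *each scan
  independently* — the target need not be the same lesion at baseline and
  follow-up — while EORTC tracks the baseline-hottest lesion forward and
  compares it with itself.
* **All lesions**: one index lesion per involved compartment (thyroid bed,
  lymph node, visceral, muscular, osseous), the compartment-hottest; the
  metric is summed over index lesions and the percent change taken on the
  sum.  The summed-metric combiner is the common multi-lesion extension of
  PERCIST; a worst-lesion combiner would make the mode redundant with the
  new-lesion and size rules.  New follow-up lesions never enter the uptake
  comparison — they fire the new-lesion rule instead.

Ties for "hottest" are broken by larger MTV, then lexicographic lesion id —
deterministic and recorded in the result's target ids.

Complete response is judged on *all* lesions, not just the target: every
non-new follow-up lesion's metric must be at or below the background level,
operationalized as the follow-up liver mean on the matching metric (SULmean
for SULpeak, SUVmean otherwise).  Using the liver as the background proxy is
a table-mode simplification; on voxel data a local background could be
substituted.

## Numerical choices

Percent changes handed to the classifier are usually reconstructed from
uptake values, so an input meant to sit exactly on a printed boundary (30%,
25%, 0.8 units, 20%) can land a few ulps away from it.  All boundary
comparisons therefore carry an absolute tolerance of 1e-8.  This makes the
printed constants exactly recoverable by behavioral sweep — the acceptance
script demonstrates this — without affecting any realistic input (the
tolerance is ~7 orders of magnitude below the data's resolution).

## The synthetic cohort generator

No per-patient PET measurements are published for the cohort this package
models, so the generator (`simulate_cohort()`) emulates the *structure* of a
25-patient, two-scan lenvatinib cohort rather than any specific patients:

* truth-class fractions CMR 0.10 / PMR 0.30 / SMD 0.25 / PMD 0.35 (the
  PERCIST 1.0 category proportions of the motivating series);
* patient-level percent uptake change drawn per class: responders
  N(−46, 25)%, progressors N(+92, 34)% (the published group-level effect
  sizes), stable N(0, 8)% (SD chosen so stable patients stay within every
  threshold);
* 8% of patients (2/25) with all lesions below the measurability floor and
  12% (3/25) with liver drift beyond the comparability limit, mutually
  exclusive with drift taking precedence;
* half of true progressors gain a new FDG-avid lesion (not reported in the
  source series; set at a clinically plausible rate);
* 1–4 lesions per patient in distinct compartments, baseline SUVmax 8–16
  (hot thyroid-cancer metastases), SUVpeak/SUVmax 0.80–0.95, a patient-level
  SUL/SUV ratio 0.70–0.85, liver SUVmean 2.2–2.8 with within-sphere SD
  0.20–0.30 — all field-typical ranges;
* optional per-lesion Gaussian noise (SD 5 percentage points by default) on
  the applied change; 0 gives an exactly noise-free cohort.

The applied change multiplies every uptake metric of a lesion by the same
factor, which preserves SUVpeak ≤ SUVmax and keeps the SUL/SUV ratio
consistent; MTV scales by the same factor and the equivalent-sphere diameter
by its cube root.  Complete responders' follow-up uptake is placed at
0.3–0.6 × the follow-up liver mean with zero residual MTV.  The injected
truth class lives in a sidecar table that no analysis stage reads.

What the generator does **not** emulate: scanner physics and reconstruction
artifacts, respiratory motion, partial-volume effects, lesion-level
heterogeneity of response within a patient (beyond the noise term), weight
change between scans, and correlated drift between lesion and liver uptake.
Passing the recovery tests therefore shows the *rule machinery* is correct,
not that the package would reproduce any particular clinical series.

The voxel-level generator (`simulate_phantom_pair()`) builds sphere phantoms
(background, liver, lesions) with multiplicative Gaussian noise (SD 5% of
the local mean by default — kept multiplicative so SUV statistics stay
positive and scale-free) and is used to exercise the quantification layer
end to end: an injected +40% uptake change is recovered as a 1.40 SUVmax
ratio by `quantify_scan()`.

Survival (`simulate_survival()`) is exponential by default (optional Weibull
shape), with hazards log(2)/35.6 and log(2)/24.9 months⁻¹ for DC and PD —
the group medians of the motivating series — and independent uniform
censoring at a configurable rate.

## Statistics

* `km_estimate()` wraps the product-limit estimator; the median is the
  smallest observed time with S(t) ≤ 0.5, "not reached" (`NA`) otherwise.
* `logrank_permutation()` computes the standard observed-minus-expected
  log-rank statistic with hypergeometric variance, but refers it to its
  permutation distribution over random relabelings of group membership
  (patients are relabeled; their (time, event) pairs stay intact), with the
  add-one correction p = (1 + #{permuted ≥ observed}) / (1 + n_perm) so p is
  never 0.  5000 permutations by default.
* `bootstrap_t()` is a studentized (Welch) bootstrap test under the shifted
  null: both samples are recentered to the pooled mean, resampled within
  group, and the two-sided p-value is the add-one-corrected fraction of
  |t*| ≥ |t_obs|.  The percentile and non-shifted variants were considered;
  the shifted studentized form was chosen because it keeps the null
  resampling distribution centered while preserving each group's variance.
* `summarize_changes()` reports per-group mean ± SD of the percent change of
  each PET parameter (uptake metrics on the baseline-hottest lesion tracked
  forward; MTV and TLG as totals over baseline lesions), with a bootstrap-t
  p-value per parameter.

All stochastic operations take an explicit seed and are bit-reproducible.

## Worked example

```{r example}
cohort <- simulate_cohort(cohort_config(n_patients = 25, seed = 1))
fit <- pet_response(cohort$lesions, cohort$liver,
                    selection = c("hottest", "all"))
summary(fit)

groups <- response_groups(fit, "eortc", "hottest")
surv <- simulate_survival(groups, seed = 2)
compare_survival(surv, n_perm = 2000, seed = 3)
```

## Problem sizes used in the test suite

The recovery tests run a 200-patient noise-free cohort with unambiguous
effect sizes (responder N(−42, 1.5)%, progressor N(+92, 10)%, stable
N(0, 4)%): declines deep enough to be unambiguous responses under every rule
set, yet shallow enough that no lesion drops below the liver background
(which would legitimately be complete resolution — at these baseline uptake
ranges that happens below roughly −52%).  The rule-table equivalence check
uses a ~10⁵-combination grid against an independently written literal
transcription of the rule table; the permutation-test calibration uses 200
null replicates of 500 permutations each.  These sizes give stable
pass/fail behavior at interactive runtimes; all statistical checks use
3-standard-error (or stated) tolerances, not exact equality.

## Known limitations

* The EORTC "extent of FDG uptake" is measured here on the longest diameter
  of the MTV delineation mask; clinical practice sometimes takes it from CT.
* The PMR absolute-decrease floor (0.8 units) is enforced only for the
  SUL-based PERCIST 1.0, where the rule's units are defined; whether
  SUVpeak/SUVmax variants should carry it is genuinely ambiguous, and the
  PMD absolute-increase floor is applied to all three PERCIST variants in
  their own metric units.
* Table-mode CMR uses the liver mean as the background proxy; voxel-mode
  local backgrounds are not implemented.
* No registration between scans, attenuation correction or automated lesion
  detection: masks/tables are taken as given.
* No covariate adjustment (Cox models) or multiplicity correction across
  rule sets; the comparison machinery intentionally mirrors unadjusted
  two-group analyses.
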