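# petresp

Metabolic tumor response classification from FDG-PET, for nuclear-medicine
and biostatistics analysts evaluating systemic therapy (for example
tyrosine-kinase-inhibitor treatment of radioiodine-refractory thyroid
cancer) with a baseline and an early follow-up PET/CT.

The package covers the whole analysis chain:

1. **Quantification** — SUVmax, SUVmean, sphere-constrained SUVpeak
   (12-mm / ~1 cm³ sphere), SULpeak (lean-body-mass or body-surface-area
   normalized), metabolic tumor volume (MTV, 42%-of-SUVmax delineation),
   total lesion glycolysis (TLG = MTV × SUVmean), longest diameter, and
   3-cm-sphere liver reference statistics — from voxel volumes (NIfTI) or
   precomputed lesion tables.
2. **Eligibility** — target-lesion measurability
   (SULpeak ≥ 1.5 × (liver SULmean + 2 SD)) and between-scan comparability
   (liver mean drift ≤ 20%), mirroring the n.a./n.c. annotations of
   clinical response tables.
3. **Classification** — four rule sets on one engine: PERCIST 1.0
   (SULpeak, ±30% with a 0.8-SUL-unit absolute condition), mPERCIST
   (SUVpeak), PERCISTmax (SUVmax), and EORTC (SUVmax, ±25%, strict >20%
   diameter progression), under hottest-lesion or all-lesions target
   selection, with CMR/PMR/SMD/PMD categories collapsed to disease control
   (DC) vs progressive disease (PD).
4. **Group comparison** — Kaplan–Meier estimates, Monte-Carlo permutation
   log-rank tests (5000 permutations by default) and shifted-null
   studentized bootstrap t-tests for per-group mean changes of the PET
   parameters.
5. **Synthetic data** — a cohort generator (lesion tables with hidden
   response truth, eligibility edge cases, group-dependent survival) and a
   voxel phantom generator, so the full pipeline runs and is tested without
   any patient data.

## Worked example

```r
library(petresp)

cohort <- simulate_cohort(cohort_config(n_patients = 25, seed = 1))
fit <- pet_response(cohort$lesions, cohort$liver,
                    selection = c("hottest", "all"))
summary(fit)
```

```
Patients: 25 
Comparability metric: suvmean | liver drift limit: 20 % | measurability multiplier: 1.5 

PERCIST 1.0  hottest  DC 14/19, PD 5 (CMR 3, PMR 4, SMD 7, PMD 5; n.a. 1, n.c. 5)
PERCIST 1.0  all      DC 14/19, PD 5 (CMR 3, PMR 4, SMD 7, PMD 5; n.a. 1, n.c. 5)
mPERCIST     hottest  DC 14/19, PD 5 (CMR 3, PMR 4, SMD 7, PMD 5; n.a. 1, n.c. 5)
mPERCIST     all      DC 14/19, PD 5 (CMR 3, PMR 4, SMD 7, PMD 5; n.a. 1, n.c. 5)
PERCISTmax   hottest  DC 14/20, PD 6 (CMR 3, PMR 4, SMD 7, PMD 6; n.a. 0, n.c. 5)
PERCISTmax   all      DC 14/20, PD 6 (CMR 3, PMR 4, SMD 7, PMD 6; n.a. 0, n.c. 5)
EORTC        hottest  DC 17/25, PD 8 (CMR 4, PMR 4, SMD 9, PMD 8; n.a. 0, n.c. 0)
EORTC        all      DC 17/25, PD 8 (CMR 4, PMR 6, SMD 7, PMD 8; n.a. 0, n.c. 0)
```

Each row is one rule set × target-selection mode: of 25 simulated patients,
the SUL/SUVpeak-based PERCIST variants can classify 19 (one patient has no
lesion above the liver measurability floor, five have liver drift beyond
20%), PERCISTmax 20, and EORTC — which is exempt from the liver drift rule —
all 25.  `DC 17/25` means 17 of the 25 classifiable patients show disease
control; the parenthesis breaks them into the four response categories.

```r
groups <- response_groups(fit, "eortc", "hottest")
surv <- simulate_survival(groups, seed = 2)
compare_survival(surv, n_perm = 2000, seed = 3)
```

```
DC (n = 17 ): median 55.18 months 
PD (n = 8 ): median 24.75 months 
Permutation log-rank p = 0.044 ( 2000 permutations )
```

Disease-controlled patients survive markedly longer than progressors
(simulated here with hazards corresponding to medians of 35.6 vs 24.9
months); the permutation log-rank test rejects equal hazards at p = 0.044.

`run_pipeline(list(seed = 42), "out/")` runs the same chain end to end and
writes all tables, JSON reports and a manifest; identical config and seed
give byte-identical artifacts.

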