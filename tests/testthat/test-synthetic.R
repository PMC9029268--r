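test_that("cohort config validates its proportions and probabilities", {
  expect_error(cohort_config(fraction_complete = 0.5), "sum to 1")
  expect_error(cohort_config(p_liver_drift_patient = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(responder_change_mean_sd = c(10, 5)), "negative")
  expect_error(cohort_config(lesions_per_patient_range = c(1, 9)), "\\[1, 5\\]")
})

test_that("generated cohorts satisfy the schema contract", {
  cohort <- simulate_cohort(cohort_config(n_patients = 25, seed = 1))
  les <- cohort$lesions
  expect_setequal(unique(les$patient_id), sprintf("P%03d", 1:25))
  for (pid in unique(les$patient_id)) {
    p <- les[les$patient_id == pid, ]
    expect_setequal(unique(p$scan), c("baseline", "followup"))
    expect_gte(sum(p$scan == "baseline"), 1)
    # every baseline lesion reappears at follow-up
    expect_true(all(p$lesion_id[p$scan == "baseline"] %in%
                      p$lesion_id[p$scan == "followup"]))
  }
  expect_true(all(les$suvpeak <= les$suvmax + 1e-12))
  expect_true(all(les$sulpeak <= les$suvpeak + 1e-12))
  expect_false(any(les$is_new[les$scan == "baseline"]))
  expect_equal(nrow(cohort$liver), 50)
  expect_equal(nrow(cohort$truth), 25)
  # validator agrees
  expect_equal(nrow(validate_lesion_table(les)), 0)
  # empty cohort: schema-valid empty tables
  empty <- simulate_cohort(cohort_config(n_patients = 0))
  expect_equal(nrow(empty$lesions), 0)
  expect_true(all(c("patient_id", "scan", "sulpeak") %in%
                    names(empty$lesions)))
})

test_that("identical seed and config give bit-identical cohorts", {
  cc <- cohort_config(n_patients = 15, seed = 99)
  expect_identical(simulate_cohort(cc), simulate_cohort(cc))
  cc2 <- cohort_config(n_patients = 15, seed = 100)
  expect_false(identical(simulate_cohort(cc), simulate_cohort(cc2)))
})

test_that("forced progression with new lesions flags every patient", {
  cc <- cohort_config(n_patients = 20, fraction_complete = 0,
                      fraction_responder = 0, fraction_stable = 0,
                      fraction_progressor = 1,
                      p_new_lesion_in_progressor = 1, seed = 2)
  cohort <- simulate_cohort(cc)
  new_by_patient <- tapply(cohort$lesions$is_new, cohort$lesions$patient_id,
                           any)
  expect_true(all(new_by_patient))
})

test_that("injected change means converge to the configured group means", {
  cc <- cohort_config(n_patients = 200, seed = 7,
                      fraction_complete = 0, fraction_stable = 0,
                      fraction_responder = 0.5, fraction_progressor = 0.5,
                      responder_change_mean_sd = c(-46, 25),
                      progressor_change_mean_sd = c(92, 34),
                      p_nonmeasurable_patient = 0, p_liver_drift_patient = 0)
  truth <- simulate_cohort(cc)$truth
  r <- truth$change_pct[truth$true_class == "PMR"]
  p <- truth$change_pct[truth$true_class == "PMD"]
  expect_lt(abs(mean(r) - (-46)), 3 * 25 / sqrt(length(r)))
  expect_lt(abs(mean(p) - 92), 3 * 34 / sqrt(length(p)))
})

test_that("phantom pairs inject the requested uptake changes", {
  spec <- phantom_spec(lesions = list(
    list(center_mm = c(24, 24, 70), radius_mm = 8, suv = 5),
    list(center_mm = c(70, 70, 24), radius_mm = 6, suv = 8)))
  # all-zero change, zero noise: follow-up identical to baseline
  p0 <- simulate_phantom_pair(spec, changes_pct = c(0, 0), noise_sd_frac = 0)
  expect_identical(p0$baseline$volume$values, p0$followup$volume$values)
  expect_identical(p0$baseline$labels, p0$followup$labels)
  # -100%: lesion voxels return to background and leave the mask
  p1 <- simulate_phantom_pair(spec, changes_pct = c(-100, 0),
                              noise_sd_frac = 0)
  les1 <- p1$baseline$labels == 2L
  expect_true(all(p1$followup$volume$values[les1] == 1))
  expect_false(any(p1$followup$labels == 2L))
  # +40% on a level-5 lesion: level 7, and quantification recovers the ratio
  p2 <- simulate_phantom_pair(spec, changes_pct = c(40, 0), noise_sd_frac = 0)
  expect_equal(max(p2$followup$volume$values[p2$followup$labels == 2L]), 7)
  qb <- quantify_scan(p2$baseline$volume, p2$baseline$labels)
  qf <- quantify_scan(p2$followup$volume, p2$followup$labels)
  expect_equal(qf$lesions$suvmax[1] / qb$lesions$suvmax[1], 1.40,
               tolerance = 1e-12)
  # new lesions appear only at follow-up; liver drift scales the reference
  p3 <- simulate_phantom_pair(spec, changes_pct = c(0, 0),
                              new_lesions = list(list(
                                center_mm = c(24, 70, 70), radius_mm = 5,
                                suv = 7)),
                              liver_drift_pct = 30, noise_sd_frac = 0)
  expect_false(any(p3$baseline$labels == 4L))
  expect_true(any(p3$followup$labels == 4L))
  liv <- p3$baseline$labels == 1L
  expect_equal(mean(p3$followup$volume$values[liv]) /
                 mean(p3$baseline$volume$values[liv]), 1.3)
  # lesions outside the grid are rejected
  expect_error(phantom_spec(lesions = list(
    list(center_mm = c(2, 2, 2), radius_mm = 10, suv = 5))),
    "inside the grid")
})

test_that("survival simulation respects hazards and censoring", {
  groups <- rep(c("DC", "PD"), each = 400)
  sv <- simulate_survival(groups, hazard_dc = log(2) / 40,
                          hazard_pd = 4 * log(2) / 40, censor_rate = 0,
                          seed = 5)
  expect_true(all(sv$event))
  m_dc <- km_estimate(sv[sv$group == "DC", ])$median_months
  m_pd <- km_estimate(sv[sv$group == "PD", ])$median_months
  # exponential median = ln 2 / hazard, so the ratio is the hazard ratio
  expect_equal(m_dc / m_pd, 4, tolerance = 0.25)
  sv2 <- simulate_survival(groups, censor_rate = 0.5, seed = 6)
  expect_gt(mean(!sv2$event), 0.35)
  expect_lt(mean(!sv2$event), 0.65)
  expect_identical(simulate_survival(groups, seed = 3),
                   simulate_survival(groups, seed = 3))
  expect_equal(nrow(simulate_survival(character(0))), 0)
  expect_error(simulate_survival(groups, hazard_dc = -1), "> 0")
})
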