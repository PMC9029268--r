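test_that("percent change is plain relative change on a positive baseline", {
  expect_equal(percent_change(5, 7), 40)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(4, 2), -50)
  expect_equal(percent_change(c(5, 4), c(7, 2)), c(40, -50))
  expect_error(percent_change(0, 1), "baseline")
  expect_error(percent_change(-2, 1), "baseline")
})

test_that("criteria specs pair each rule set with its metric and thresholds", {
  expect_equal(criteria_spec("percist10")$metric, "sulpeak")
  expect_equal(criteria_spec("mpercist")$metric, "suvpeak")
  expect_equal(criteria_spec("percistmax")$metric, "suvmax")
  expect_equal(criteria_spec("eortc")$metric, "suvmax")
  expect_equal(criteria_spec("eortc")$pmd_pct, 25)
  expect_equal(criteria_spec("percist10")$pmd_pct, 30)
  expect_error(criteria_spec("percist10", pmd_pct = -5), "must be > 0")
  expect_error(criteria_spec("percist10", nonsense = 1), "unknown")
})

test_that("PERCIST-family classification honors the conjunctive progression rule", {
  sp <- criteria_spec("percist10")
  # +40% and +2.0 units -> progression
  expect_equal(as.character(classify_percist_family(sp, 5, 7)), "PMD")
  # +35% but only +0.7 units -> absolute floor not met -> stable
  expect_equal(as.character(classify_percist_family(sp, 2, 2.7)), "SMD")
  # -40% and -2.0 units -> response
  expect_equal(as.character(classify_percist_family(sp, 5, 3)), "PMR")
  # stable uptake but a new avid lesion -> progression regardless
  expect_equal(as.character(classify_percist_family(sp, 5, 5,
                                                    new_lesions = TRUE)),
               "PMD")
  # size progression alone is sufficient
  expect_equal(as.character(
    classify_percist_family(sp, 5, 5, target_size_change_pct = 30)), "PMD")
  # SUL-based PMR needs an absolute decrease of 0.8 units too
  expect_equal(as.character(classify_percist_family(sp, 1.0, 0.6)), "SMD")
  sp_pk <- criteria_spec("mpercist")
  expect_equal(as.character(classify_percist_family(sp_pk, 1.0, 0.6)), "PMR")
  # resolution to background wins over PMR but loses to progression
  expect_equal(as.character(
    classify_percist_family(sp, 5, 1.2, background_level = 1.5)), "CMR")
  expect_equal(as.character(
    classify_percist_family(sp, 5, 1.2, new_lesions = TRUE,
                            background_level = 1.5)), "PMD")
})

test_that("EORTC classification uses 25% uptake and strict 20% diameter rules", {
  expect_equal(as.character(classify_eortc(6, 7.5)), "PMD")   # +25 inclusive
  expect_equal(as.character(classify_eortc(6, 4.5)), "PMR")   # -25 inclusive
  expect_equal(as.character(classify_eortc(6, 6.6)), "SMD")   # +10
  expect_equal(as.character(
    classify_eortc(6, 6.6, longest_diameter_change_pct = 30)), "PMD")
  expect_equal(as.character(
    classify_eortc(6, 6.0, longest_diameter_change_pct = 20)), "SMD")
  expect_warning(
    cat_na <- classify_eortc(6, 6.0, longest_diameter_change_pct = NA),
    "uptake alone")
  expect_equal(as.character(cat_na), "SMD")
  expect_equal(as.character(classify_eortc(6, 1.5, all_resolved = TRUE)),
               "CMR")
})

test_that("dichotomy maps PMD to PD and everything else to DC", {
  expect_equal(as.character(dichotomize(c("CMR", "PMR", "SMD", "PMD"))),
               c("DC", "DC", "DC", "PD"))
  expect_error(dichotomize("XYZ"), "invalid")
})

test_that("target selection follows per-scan vs baseline-tracked conventions", {
  b <- data.frame(lesion_id = c("A", "B"), compartment = "lymph_node",
                  suvmax = c(8, 5), mtv_cm3 = c(2, 2))
  f <- data.frame(lesion_id = c("A", "B"), compartment = "lymph_node",
                  suvmax = c(4, 6), mtv_cm3 = c(2, 2), is_new = FALSE)
  # PERCIST: hottest of each scan independently -> 8 vs 6 (-25%)
  tp <- select_target(b, f, "suvmax", "hottest", "percistmax")
  expect_equal(percent_change(tp$base, tp$follow), -25)
  expect_equal(tp$follow_ids, "B")
  # EORTC: the baseline-hottest lesion tracked forward -> 8 vs 4 (-50%)
  te <- select_target(b, f, "suvmax", "hottest", "eortc")
  expect_equal(percent_change(te$base, te$follow), -50)
  expect_equal(te$follow_ids, "A")
  # single-lesion patients: conventions coincide
  b1 <- b[1, ]; f1 <- f[1, ]
  for (cr in c("percist10", "eortc")) {
    t1 <- select_target(b1, f1, "suvmax", "hottest", cr)
    expect_equal(c(t1$base, t1$follow), c(8, 4))
    ta <- select_target(b1, f1, "suvmax", "all", cr)
    expect_equal(c(ta$base, ta$follow), c(8, 4))
  }
  # all-lesions mode sums one index lesion per compartment
  b2 <- b; b2$compartment <- c("lymph_node", "visceral")
  f2 <- f; f2$compartment <- c("lymph_node", "visceral")
  ta2 <- select_target(b2, f2, "suvmax", "all", "percistmax")
  expect_equal(c(ta2$base, ta2$follow), c(13, 10))
  # ties broken by larger MTV then lexicographic id
  bt <- data.frame(lesion_id = c("B", "A"), compartment = "visceral",
                   suvmax = c(7, 7), mtv_cm3 = c(1, 3))
  expect_equal(select_target(bt, f, "suvmax", "hottest", "eortc")$base_ids, "A")
})

test_that("classification is monotone: hotter follow-up never looks better", {
  rank_of <- c(CMR = 0, PMR = 1, SMD = 2, PMD = 3)
  follows <- seq(0.5, 12, by = 0.1)
  for (cr in c("percist10", "mpercist", "percistmax", "eortc")) {
    sp <- criteria_spec(cr)
    cats <- if (cr == "eortc")
      classify_eortc(5, follows, background_level = 1.5, spec = sp)
    else classify_percist_family(sp, 5, follows, background_level = 1.5)
    expect_true(all(diff(rank_of[as.character(cats)]) >= 0), label = cr)
  }
})

test_that("engine matches the literal rule-table transcription on a mixed grid", {
  set.seed(11)
  n <- 4000
  base <- runif(n, 0.5, 12)
  follow <- base * (1 + runif(n, -0.95, 1.5))
  new_l <- runif(n) < 0.1
  size <- sample(c(0, 10, 20, 25, 30, 45), n, replace = TRUE)
  for (cr in c("percist10", "mpercist", "percistmax", "eortc")) {
    sp <- criteria_spec(cr)
    got <- if (cr == "eortc")
      classify_eortc(base, follow, new_l, size, all_resolved = FALSE, spec = sp)
    else classify_percist_family(sp, base, follow, new_l, size,
                                 all_resolved = FALSE)
    want <- mapply(oracle_classify, criteria = cr, base = base,
                   follow = follow, new_lesion = new_l, size_change = size)
    expect_identical(as.character(got), unname(want), label = cr)
  }
})

test_that("cohort classification recovers injected truth on a noise-free cohort", {
  cohort <- simulate_cohort(unambiguous_config(120, seed = 9))
  fit <- pet_response(cohort$lesions, cohort$liver,
                      selection = c("hottest", "all"))
  res <- merge(fit$results, cohort$truth, by = "patient_id")
  expect_true(all(res$status == "ok"))
  expect_identical(res$category, res$true_class)
  # hottest vs all never disagree here (one shared change per patient)
  wide <- split(res$category, res$selection)
  expect_identical(wide$hottest, wide$all)
})

test_that("all-progressor cohorts yield zero disease control", {
  cc <- cohort_config(n_patients = 30, fraction_complete = 0,
                      fraction_responder = 0, fraction_stable = 0,
                      fraction_progressor = 1,
                      p_new_lesion_in_progressor = 1,
                      p_nonmeasurable_patient = 0, p_liver_drift_patient = 0,
                      noise_sd_pct = 0, seed = 3)
  cohort <- simulate_cohort(cc)
  fit <- pet_response(cohort$lesions, cohort$liver, criteria = "eortc")
  expect_true(all(fit$results$dichotomy == "PD"))
})

test_that("non-comparable patients drop from PERCIST counts but stay in EORTC", {
  tabs <- make_patient_tables(c(10, 8), c(4, 3.5),
                              liver_suv_b = 2.0, liver_suv_f = 2.5)  # 25% drift
  fit <- pet_response(tabs$lesions, tabs$liver)
  r <- fit$results
  expect_equal(r$status[r$criteria == "percist10"], "not_comparable")
  expect_equal(r$status[r$criteria == "percistmax"], "not_comparable")
  expect_equal(r$status[r$criteria == "eortc"], "ok")
  expect_equal(r$category[r$criteria == "eortc"], "PMR")
  expect_error(pet_response(rbind(tabs$lesions, tabs$lesions[1, ]),
                            tabs$liver),
               "duplicate")
})
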