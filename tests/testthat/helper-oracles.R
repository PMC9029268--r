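# Independent oracles used across the suite.

# Literal transcription of the published response rule table, evaluated as a
# scalar lookup with explicit precedence (new lesion / progression first).
# Shares the package's printed-threshold comparison convention (absolute
# tolerance 1e-8) so that boundary inputs reconstructed from rounded uptake
# values are judged identically; the rule logic and precedence are written
# independently of the package internals.
oracle_eps <- 1e-8
oracle_classify <- function(criteria, base, follow, new_lesion = FALSE,
                            size_change = 0, resolved = FALSE) {
  pct <- 100 * (follow - base) / base
  abs_chg <- follow - base
  if (criteria == "eortc") {
    # PMD: SUVmax increase of at least 25%, OR >20% in longest diameter,
    #      OR new FDG-avid lesion
    if (pct >= 25 - oracle_eps) return("PMD")
    if (size_change > 20 + oracle_eps) return("PMD")
    if (new_lesion) return("PMD")
    # CMR: complete resolution of FDG uptake in all lesions
    if (resolved) return("CMR")
    # PMR: decrease in SUVmax of at least 25%
    if (pct <= -25 + oracle_eps) return("PMR")
    return("SMD")
  }
  # PERCIST family (metric: SULpeak / SUVpeak / SUVmax)
  # PMD: increase of at least 30% AND absolute increase of at least 0.8
  #      units, OR target lesion size increase by 30%, OR new lesion
  if (pct >= 30 - oracle_eps && abs_chg >= 0.8 - oracle_eps) return("PMD")
  if (size_change >= 30 - oracle_eps) return("PMD")
  if (new_lesion) return("PMD")
  if (resolved) return("CMR")
  # PMR: decrease of at least 30%; PERCIST 1.0 (SUL units) additionally a
  #      decrease of at least 0.8 units
  if (pct <= -30 + oracle_eps) {
    if (criteria == "percist10" && !(abs_chg <= -0.8 + oracle_eps))
      return("SMD")
    return("PMR")
  }
  "SMD"
}

# Exhaustive sphere-peak search: for every mask voxel as candidate center,
# average all grid voxels whose centers fall inside the sphere, by direct
# distance computation over the full grid.
oracle_suv_peak <- function(values, spacing, mask, sphere_diameter_mm = 12) {
  dims <- dim(values)
  r2 <- (sphere_diameter_mm / 2)^2
  centers <- which(mask != 0, arr.ind = TRUE)
  grid <- which(array(TRUE, dims), arr.ind = TRUE)
  gx <- (grid[, 1] - 0.5) * spacing[1]
  gy <- (grid[, 2] - 0.5) * spacing[2]
  gz <- (grid[, 3] - 0.5) * spacing[3]
  best <- -Inf
  for (c in seq_len(nrow(centers))) {
    cx <- (centers[c, 1] - 0.5) * spacing[1]
    cy <- (centers[c, 2] - 0.5) * spacing[2]
    cz <- (centers[c, 3] - 0.5) * spacing[3]
    inside <- (gx - cx)^2 + (gy - cy)^2 + (gz - cz)^2 <= r2 + 1e-9
    best <- max(best, mean(values[inside]))
  }
  best
}

# All-pairs longest diameter over voxel centers.
oracle_longest_diameter <- function(mask, spacing) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) < 2) return(0)
  xyz <- sweep(idx - 0.5, 2, spacing, "*")
  best <- 0
  for (a in seq_len(nrow(xyz) - 1)) {
    d <- sqrt(colSums((t(xyz[(a + 1):nrow(xyz), , drop = FALSE]) - xyz[a, ])^2))
    best <- max(best, d)
  }
  best
}

# Logical mask of voxels whose centers fall within a sphere (voxel centers
# at (i - 0.5) * spacing).
sphere_voxels_helper <- function(dims, spacing, center_mm, radius_mm) {
  cx <- (seq_len(dims[1]) - 0.5) * spacing[1]
  cy <- (seq_len(dims[2]) - 0.5) * spacing[2]
  cz <- (seq_len(dims[3]) - 0.5) * spacing[3]
  d2 <- outer(outer((cx - center_mm[1])^2, (cy - center_mm[2])^2, "+"),
              (cz - center_mm[3])^2, "+")
  d2 <= radius_mm^2
}

# Minimal single-patient lesion/liver tables for classification tests.
make_patient_tables <- function(base_vals, follow_vals,
                                base_diam = 20, follow_diam = 20,
                                new_lesion = FALSE, sul_ratio = 0.8,
                                liver_suv_b = 2.5, liver_suv_f = 2.5,
                                liver_sd = 0.25, pid = "P001") {
  n <- length(base_vals)
  ids <- paste0(pid, "_L", seq_len(n))
  comps <- rep_len(c("lymph_node", "visceral", "osseous", "muscular",
                     "thyroid_bed"), n)
  mk <- function(scan, vals, diam, is_new = FALSE, id = ids, comp = comps) {
    data.frame(patient_id = pid, scan = scan, lesion_id = id,
               compartment = comp, suvmax = vals, suvmean = vals * 0.6,
               suvpeak = vals * 0.9, sulpeak = vals * 0.9 * sul_ratio,
               mtv_cm3 = rep_len(5, length(vals)),
               longest_diameter_mm = rep_len(diam, length(vals)),
               is_new = is_new, stringsAsFactors = FALSE)
  }
  lesions <- rbind(mk("baseline", base_vals, base_diam),
                   mk("followup", follow_vals, follow_diam))
  if (new_lesion)
    lesions <- rbind(lesions,
                     mk("followup", 10, 15, is_new = TRUE,
                        id = paste0(pid, "_new"), comp = "visceral"))
  liver <- data.frame(patient_id = pid, scan = c("baseline", "followup"),
                      liver_suvmean = c(liver_suv_b, liver_suv_f),
                      liver_suv_sd = liver_sd,
                      liver_sulmean = c(liver_suv_b, liver_suv_f) * sul_ratio,
                      liver_sul_sd = liver_sd * sul_ratio,
                      stringsAsFactors = FALSE)
  list(lesions = lesions, liver = liver)
}

# Unambiguous-effect-size cohort configuration used by the recovery tests:
# class-conditional changes far from every decision boundary, no
# eligibility flags, no noise.  Responder declines sit well beyond the
# -30%/-25% response thresholds but above the level where a lesion's
# follow-up uptake could fall below the liver background (which would
# legitimately read as complete resolution rather than partial response).
unambiguous_config <- function(n_patients, seed) {
  cohort_config(n_patients = n_patients, seed = seed,
                responder_change_mean_sd = c(-42, 1.5),
                progressor_change_mean_sd = c(92, 10),
                stable_change_mean_sd = c(0, 4),
                p_nonmeasurable_patient = 0, p_liver_drift_patient = 0,
                noise_sd_pct = 0)
}
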