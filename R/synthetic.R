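#' Configuration for the synthetic lesion-table cohort generator
#'
#' Defines the statistical structure of a two-scan longitudinal FDG-PET
#' cohort: the mix of true response classes, the class-conditional percent
#' uptake changes, and the rates of the two data problems the eligibility
#' screen must catch (lesions below the measurability floor, liver
#' reference drift beyond the comparability limit).  Defaults mirror a
#' 25-patient lenvatinib-treated thyroid-cancer cohort: truth fractions
#' CMR 0.10 / PMR 0.30 / SMD 0.25 / PMD 0.35, responder change
#' N(-46, 25)%, progressor change N(+92, 34)%, 2/25 patients without a
#' measurable peak and 3/25 with liver drift.
#'
#' @param n_patients number of patients.
#' @param fraction_complete,fraction_responder,fraction_stable,fraction_progressor
#'   truth-class proportions (CMR/PMR/SMD/PMD); must sum to 1.
#' @param responder_change_mean_sd,progressor_change_mean_sd,stable_change_mean_sd
#'   length-2 `c(mean, sd)` of the class-conditional percent uptake change.
#' @param p_new_lesion_in_progressor probability that a true progressor
#'   gains a new FDG-avid lesion at follow-up.
#' @param p_nonmeasurable_patient probability that all of a patient's
#'   lesions sit below the SULpeak/SUVpeak measurability floor.
#' @param p_liver_drift_patient probability of liver reference drift
#'   beyond the 20% comparability limit (mutually exclusive with the
#'   non-measurable flag; drift takes precedence).
#' @param lesions_per_patient_range integer range `c(min, max)`, max 5
#'   (one compartment per lesion).
#' @param noise_sd_pct SD (percentage points) of per-lesion noise added to
#'   the patient-level percent change; 0 gives a noise-free cohort.
#' @param seed RNG seed; a fixed seed makes the cohort bit-identical.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 25,
                          fraction_complete = 0.10,
                          fraction_responder = 0.30,
                          fraction_stable = 0.25,
                          fraction_progressor = 0.35,
                          responder_change_mean_sd = c(-46, 25),
                          progressor_change_mean_sd = c(92, 34),
                          stable_change_mean_sd = c(0, 8),
                          p_new_lesion_in_progressor = 0.5,
                          p_nonmeasurable_patient = 0.08,
                          p_liver_drift_patient = 0.12,
                          lesions_per_patient_range = c(1, 4),
                          noise_sd_pct = 5,
                          seed = 1) {
  fr <- c(fraction_complete, fraction_responder, fraction_stable,
          fraction_progressor)
  if (abs(sum(fr) - 1) > 1e-9) stop("truth-class fractions must sum to 1")
  if (any(fr < 0)) stop("truth-class fractions must be >= 0")
  probs <- c(p_new_lesion_in_progressor, p_nonmeasurable_patient,
             p_liver_drift_patient)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (responder_change_mean_sd[1] >= 0)
    stop("responder change mean must be negative")
  if (progressor_change_mean_sd[1] <= 0)
    stop("progressor change mean must be positive")
  rng <- as.integer(lesions_per_patient_range)
  if (length(rng) != 2 || rng[1] < 1 || rng[2] < rng[1] || rng[2] > 5)
    stop("lesions_per_patient_range must be within [1, 5]")
  structure(list(n_patients = as.integer(n_patients),
                 fraction_complete = fraction_complete,
                 fraction_responder = fraction_responder,
                 fraction_stable = fraction_stable,
                 fraction_progressor = fraction_progressor,
                 responder_change_mean_sd = responder_change_mean_sd,
                 progressor_change_mean_sd = progressor_change_mean_sd,
                 stable_change_mean_sd = stable_change_mean_sd,
                 p_new_lesion_in_progressor = p_new_lesion_in_progressor,
                 p_nonmeasurable_patient = p_nonmeasurable_patient,
                 p_liver_drift_patient = p_liver_drift_patient,
                 lesions_per_patient_range = rng,
                 noise_sd_pct = noise_sd_pct,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

compartment_pool <- c("thyroid_bed", "lymph_node", "visceral", "muscular",
                      "osseous")

empty_lesion_table <- function() {
  data.frame(patient_id = character(), scan = character(),
             lesion_id = character(), compartment = character(),
             suvmax = numeric(), suvmean = numeric(), suvpeak = numeric(),
             sulpeak = numeric(), mtv_cm3 = numeric(),
             longest_diameter_mm = numeric(), is_new = logical(),
             stringsAsFactors = FALSE)
}

# equivalent-sphere diameter (mm) for a volume in cm^3
mtv_to_diameter <- function(mtv_cm3) 2 * (3 * mtv_cm3 * 1000 / (4 * pi))^(1 / 3)

#' Generate a synthetic longitudinal lesion-table cohort
#'
#' Draws, per patient: a hidden truth class (CMR/PMR/SMD/PMD by the
#' configured fractions), 1-5 lesions in distinct compartments with
#' baseline uptake metrics, per-scan liver reference statistics, and
#' follow-up values obtained by applying the class-conditional percent
#' change (plus optional per-lesion noise) to every uptake metric.
#' Designated patients get lesions below the measurability floor or liver
#' drift beyond the comparability limit; true progressors may gain a new
#' follow-up lesion.  The truth table is a sidecar never read by the
#' analysis stages.
#'
#' @param config a [cohort_config()].
#' @return list with `lesions` (the lesion table; see
#'   [pet_response()] for the schema), `liver` (per-scan liver reference
#'   rows), `patients` (attributes: weight, height, sex, injected
#'   activity), and `truth` (sidecar: `patient_id`, `true_class`,
#'   `change_pct` — the drawn patient-level change, `NA` for CMR —,
#'   `nonmeasurable`, `liver_drift`, `new_lesion`).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 5, seed = 7))
#' head(cohort$lesions)
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  if (n == 0) {
    return(list(lesions = empty_lesion_table(),
                liver = data.frame(patient_id = character(), scan = character(),
                                   liver_suvmean = numeric(),
                                   liver_suv_sd = numeric(),
                                   liver_sulmean = numeric(),
                                   liver_sul_sd = numeric()),
                patients = data.frame(patient_id = character(),
                                      weight_kg = numeric(),
                                      height_cm = numeric(), sex = character(),
                                      injected_activity_mbq = numeric()),
                truth = data.frame(patient_id = character(),
                                   true_class = character(),
                                   change_pct = numeric(),
                                   nonmeasurable = logical(),
                                   liver_drift = logical(),
                                   new_lesion = logical())))
  }
  classes <- sample(c("CMR", "PMR", "SMD", "PMD"), n, replace = TRUE,
                    prob = c(config$fraction_complete,
                             config$fraction_responder,
                             config$fraction_stable,
                             config$fraction_progressor))
  lesions <- list(); liver <- list(); patients <- list(); truth <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    cls <- classes[i]
    drift <- stats::runif(1) < config$p_liver_drift_patient
    nonmeas <- !drift && stats::runif(1) < config$p_nonmeasurable_patient

    sex <- sample(c("male", "female"), 1)
    weight <- stats::runif(1, 55, 95)
    height <- stats::runif(1, 155, 190)
    sul_ratio <- stats::runif(1, 0.70, 0.85)
    patients[[i]] <- data.frame(patient_id = pid, weight_kg = weight,
                                height_cm = height, sex = sex,
                                injected_activity_mbq = 4 * weight,
                                stringsAsFactors = FALSE)

    liv_suv_b <- stats::runif(1, 2.2, 2.8)
    liv_sd_b <- stats::runif(1, 0.20, 0.30)
    drift_factor <- if (drift) 1 + sample(c(-1, 1), 1) * stats::runif(1, 0.25, 0.40)
                    else 1 + stats::runif(1, -0.10, 0.10)
    liv_suv_f <- liv_suv_b * drift_factor
    liv_sd_f <- liv_sd_b * stats::runif(1, 0.9, 1.1)
    liver[[i]] <- data.frame(
      patient_id = pid, scan = c("baseline", "followup"),
      liver_suvmean = c(liv_suv_b, liv_suv_f),
      liver_suv_sd = c(liv_sd_b, liv_sd_f),
      liver_sulmean = c(liv_suv_b, liv_suv_f) * sul_ratio,
      liver_sul_sd = c(liv_sd_b, liv_sd_f) * sul_ratio,
      stringsAsFactors = FALSE)

    n_les <- sample(seq(config$lesions_per_patient_range[1],
                        config$lesions_per_patient_range[2]), 1)
    comps <- sample(compartment_pool, n_les)
    suvmax_b <- if (nonmeas) stats::runif(n_les, 2.0, 3.2)
                else stats::runif(n_les, 8, 16)
    peak_ratio <- stats::runif(n_les, 0.80, 0.95)
    mean_ratio <- stats::runif(n_les, 0.55, 0.70)
    suvpeak_b <- suvmax_b * peak_ratio
    suvmean_b <- suvmax_b * mean_ratio
    mtv_b <- stats::runif(n_les, 2, 30)
    diam_b <- mtv_to_diameter(mtv_b)

    change <- switch(cls,
      CMR = NA_real_,
      PMR = stats::rnorm(1, config$responder_change_mean_sd[1],
                         config$responder_change_mean_sd[2]),
      SMD = stats::rnorm(1, config$stable_change_mean_sd[1],
                         config$stable_change_mean_sd[2]),
      PMD = stats::rnorm(1, config$progressor_change_mean_sd[1],
                         config$progressor_change_mean_sd[2]))

    if (cls == "CMR") {
      resid <- liv_suv_f * stats::runif(n_les, 0.30, 0.60)
      suvmax_f <- resid
      suvpeak_f <- resid * 0.9
      suvmean_f <- resid * 0.8
      mtv_f <- rep(0, n_les)
      diam_f <- rep(0, n_les)
    } else {
      applied <- pmax(change + stats::rnorm(n_les, 0, config$noise_sd_pct), -95)
      factor_f <- 1 + applied / 100
      suvmax_f <- suvmax_b * factor_f
      suvpeak_f <- suvpeak_b * factor_f
      suvmean_f <- suvmean_b * factor_f
      mtv_f <- mtv_b * factor_f
      diam_f <- diam_b * factor_f^(1 / 3)
    }

    lesion_ids <- sprintf("%s_L%d", pid, seq_len(n_les))
    lesions[[length(lesions) + 1L]] <- data.frame(
      patient_id = pid, scan = "baseline", lesion_id = lesion_ids,
      compartment = comps, suvmax = suvmax_b, suvmean = suvmean_b,
      suvpeak = suvpeak_b, sulpeak = suvpeak_b * sul_ratio,
      mtv_cm3 = mtv_b, longest_diameter_mm = diam_b, is_new = FALSE,
      stringsAsFactors = FALSE)
    lesions[[length(lesions) + 1L]] <- data.frame(
      patient_id = pid, scan = "followup", lesion_id = lesion_ids,
      compartment = comps, suvmax = suvmax_f, suvmean = suvmean_f,
      suvpeak = suvpeak_f, sulpeak = suvpeak_f * sul_ratio,
      mtv_cm3 = mtv_f, longest_diameter_mm = diam_f, is_new = FALSE,
      stringsAsFactors = FALSE)

    new_lesion <- cls == "PMD" &&
      stats::runif(1) < config$p_new_lesion_in_progressor
    if (new_lesion) {
      smax <- stats::runif(1, 8, 16)
      nl_mtv <- stats::runif(1, 1, 10)
      lesions[[length(lesions) + 1L]] <- data.frame(
        patient_id = pid, scan = "followup",
        lesion_id = sprintf("%s_new1", pid),
        compartment = sample(compartment_pool, 1),
        suvmax = smax, suvmean = smax * 0.6, suvpeak = smax * 0.85,
        sulpeak = smax * 0.85 * sul_ratio, mtv_cm3 = nl_mtv,
        longest_diameter_mm = mtv_to_diameter(nl_mtv), is_new = TRUE,
        stringsAsFactors = FALSE)
    }

    truth[[i]] <- data.frame(patient_id = pid, true_class = cls,
                             change_pct = change, nonmeasurable = nonmeas,
                             liver_drift = drift, new_lesion = new_lesion,
                             stringsAsFactors = FALSE)
  }
  list(lesions = do.call(rbind, lesions),
       liver = do.call(rbind, liver),
       patients = do.call(rbind, patients),
       truth = do.call(rbind, truth))
}

#' Specification of a two-scan voxel phantom
#'
#' Geometry of a synthetic PET volume: a noisy background, a spherical
#' liver, and spherical lesions at given SUV levels.  All spheres must lie
#' fully inside the grid.
#'
#' @param grid_shape voxels per axis (length 3).
#' @param spacing_mm mm per axis (length 3).
#' @param background_suv background SUV level.
#' @param liver_center_mm,liver_radius_mm liver sphere (radius > 0); the
#'   default radius 25 mm accommodates the 30-mm reference sphere.
#' @param liver_suv liver SUV level.
#' @param lesions list of `list(center_mm =, radius_mm =, suv =)` entries.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48), spacing_mm = c(2, 2, 2),
                         background_suv = 1, liver_center_mm = NULL,
                         liver_radius_mm = 25, liver_suv = 2.5,
                         lesions = list()) {
  extent <- grid_shape * spacing_mm
  if (is.null(liver_center_mm)) liver_center_mm <- extent / 2
  check_sphere <- function(center, radius, what) {
    if (radius <= 0) stop(what, " radius must be > 0")
    if (any(center - radius < 0) || any(center + radius > extent))
      stop(what, " sphere does not lie fully inside the grid")
  }
  check_sphere(liver_center_mm, liver_radius_mm, "liver")
  for (k in seq_along(lesions))
    check_sphere(lesions[[k]]$center_mm, lesions[[k]]$radius_mm,
                 paste0("lesion ", k))
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 background_suv = background_suv,
                 liver_center_mm = liver_center_mm,
                 liver_radius_mm = liver_radius_mm, liver_suv = liver_suv,
                 lesions = lesions),
            class = "phantom_spec")
}

sphere_voxels <- function(grid_shape, spacing, center_mm, radius_mm) {
  cx <- axis_centers(grid_shape[1], spacing[1])
  cy <- axis_centers(grid_shape[2], spacing[2])
  cz <- axis_centers(grid_shape[3], spacing[3])
  d2 <- outer(outer((cx - center_mm[1])^2, (cy - center_mm[2])^2, "+"),
              (cz - center_mm[3])^2, "+")
  d2 <= radius_mm^2
}

build_phantom <- function(spec, lesion_levels, extra_lesions = list(),
                          liver_factor = 1) {
  vals <- array(spec$background_suv, spec$grid_shape)
  labels <- array(0L, spec$grid_shape)
  liv <- sphere_voxels(spec$grid_shape, spec$spacing_mm,
                       spec$liver_center_mm, spec$liver_radius_mm)
  vals[liv] <- spec$liver_suv * liver_factor
  labels[liv] <- 1L
  all_lesions <- c(spec$lesions, extra_lesions)
  for (k in seq_along(all_lesions)) {
    le <- all_lesions[[k]]
    inside <- sphere_voxels(spec$grid_shape, spec$spacing_mm,
                            le$center_mm, le$radius_mm)
    level <- if (k <= length(lesion_levels)) lesion_levels[k] else le$suv
    if (level > spec$background_suv) {
      vals[inside] <- level
      labels[inside] <- k + 1L
    }
  }
  list(values = vals, labels = labels)
}

#' Generate a baseline/follow-up phantom pair
#'
#' Builds two voxel volumes with integer label masks (0 background,
#' 1 liver, lesions from 2).  Follow-up lesion levels equal baseline
#' levels times `(1 + change/100)` before noise; a -100% change returns
#' the lesion's voxels to background (and removes it from the follow-up
#' mask); new lesions appear only in the follow-up; the liver level is
#' scaled by `1 + liver_drift_pct/100`.  Noise is multiplicative Gaussian
#' on voxel values with SD `noise_sd_frac` of the local mean.
#'
#' @param spec a [phantom_spec()].
#' @param changes_pct numeric vector, percent uptake change per lesion in
#'   `spec$lesions` (recycled).
#' @param new_lesions list of extra lesion specs added at follow-up only.
#' @param liver_drift_pct percent change of the liver level.
#' @param noise_sd_frac noise SD as fraction of the local mean (default
#'   0.05; 0 disables noise).
#' @param seed RNG seed.
#' @return list with `baseline` and `followup`, each a list of `volume`
#'   (a `"SUV"` [voxel_volume()]) and `labels` (integer array).
#' @export
simulate_phantom_pair <- function(spec, changes_pct = 0, new_lesions = list(),
                                  liver_drift_pct = 0, noise_sd_frac = 0.05,
                                  seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_les <- length(spec$lesions)
  changes_pct <- rep_len(changes_pct, max(n_les, 1L))
  if (n_les == 0) changes_pct <- numeric(0)
  for (nl in new_lesions) {
    # validate against the grid like spec lesions
    phantom_spec(spec$grid_shape, spec$spacing_mm, spec$background_suv,
                 spec$liver_center_mm, spec$liver_radius_mm, spec$liver_suv,
                 list(nl))
  }
  set.seed(seed)
  base_levels <- vapply(spec$lesions, function(l) l$suv, 0)
  follow_levels <- base_levels * (1 + changes_pct / 100)
  follow_levels[changes_pct <= -100] <- spec$background_suv
  b <- build_phantom(spec, base_levels)
  f <- build_phantom(spec, c(follow_levels,
                             vapply(new_lesions, function(l) l$suv, 0)),
                     extra_lesions = new_lesions,
                     liver_factor = 1 + liver_drift_pct / 100)
  add_noise <- function(vals) {
    if (noise_sd_frac <= 0) return(vals)
    vals * (1 + stats::rnorm(length(vals), 0, noise_sd_frac))
  }
  sp <- spec$spacing_mm
  list(baseline = list(volume = voxel_volume(add_noise(b$values), sp, "SUV"),
                       labels = b$labels),
       followup = list(volume = voxel_volume(add_noise(f$values), sp, "SUV"),
                       labels = f$labels))
}

#' Simulate group-dependent survival records
#'
#' Event times are drawn from an exponential (or Weibull, via `shape`)
#' distribution with a group-specific hazard; censoring is independent:
#' with probability `censor_rate` a record is censored at a uniform time
#' before its event.  Default hazards correspond to median
#' progression-free survival of 35.6 months (DC) and 24.9 months (PD).
#'
#' @param groups data.frame with `patient_id` and `group` (`DC`/`PD`), or
#'   a character vector of groups.
#' @param hazard_dc,hazard_pd hazards (1/months, > 0).
#' @param censor_rate probability of censoring, in [0, 1).
#' @param shape Weibull shape (1 = exponential).
#' @param seed RNG seed.
#' @return data.frame: `patient_id`, `time_months`, `event` (logical),
#'   `group`.
#' @export
simulate_survival <- function(groups, hazard_dc = log(2) / 35.6,
                              hazard_pd = log(2) / 24.9,
                              censor_rate = 0, shape = 1, seed = 1) {
  if (is.character(groups) || is.factor(groups))
    groups <- data.frame(patient_id = sprintf("P%03d", seq_along(groups)),
                         group = as.character(groups),
                         stringsAsFactors = FALSE)
  if (nrow(groups) == 0)
    return(data.frame(patient_id = character(), time_months = numeric(),
                      event = logical(), group = character()))
  if (hazard_dc <= 0 || hazard_pd <= 0) stop("hazards must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  if (!all(groups$group %in% c("DC", "PD")))
    stop("groups must be 'DC' or 'PD'")
  set.seed(seed)
  hz <- ifelse(groups$group == "PD", hazard_pd, hazard_dc)
  t_event <- if (shape == 1) stats::rexp(nrow(groups), hz)
             else stats::rweibull(nrow(groups), shape = shape, scale = 1 / hz)
  censored <- stats::runif(nrow(groups)) < censor_rate
  time <- ifelse(censored, stats::runif(nrow(groups)) * t_event, t_event)
  data.frame(patient_id = groups$patient_id, time_months = time,
             event = !censored, group = groups$group,
             stringsAsFactors = FALSE)
}
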