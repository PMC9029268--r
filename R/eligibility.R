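#' Liver reference statistics for one scan
#'
#' Container for the mean and standard deviation of SUL and SUV inside a
#' 3-cm spherical region of interest placed in the normal right liver lobe.
#' These statistics define the measurability floor for target lesions and
#' the between-scan comparability check.
#'
#' @param sulmean,sul_sd mean and (population) SD of SUL in the sphere.
#' @param suvmean,suv_sd mean and (population) SD of SUV in the sphere.
#' @param sphere_diameter_mm sphere diameter, default 30 mm.
#' @return object of class `liver_reference`.
#' @export
liver_ref <- function(sulmean, sul_sd, suvmean, suv_sd = NA_real_,
                      sphere_diameter_mm = 30) {
  stopifnot(is.numeric(sulmean), is.numeric(sul_sd),
            is.na(sul_sd) || sul_sd >= 0)
  structure(list(sulmean = sulmean, sul_sd = sul_sd,
                 suvmean = suvmean, suv_sd = suv_sd,
                 sphere_diameter_mm = sphere_diameter_mm),
            class = "liver_reference")
}

liver_floor <- function(liver, metric = c("sul", "suv"), multiplier = 1.5) {
  metric <- match.arg(metric)
  m <- if (metric == "sul") liver$sulmean else liver$suvmean
  s <- if (metric == "sul") liver$sul_sd else liver$suv_sd
  if (is.null(m) || is.na(m)) stop("liver reference mean (", metric, ") missing")
  if (is.null(s) || is.na(s)) stop("liver reference SD (", metric, ") missing")
  multiplier * (m + 2 * s)
}

#' Target-lesion measurability against the liver background floor
#'
#' A target lesion is measurable when its SULpeak is at least `multiplier`
#' (default 1.5) times the liver reference SULmean plus two standard
#' deviations of a 3-cm sphere in the normal right liver lobe.  The
#' boundary is inclusive ("at least").
#'
#' @param lesion_sulpeak lesion SULpeak (or the rule set's own peak metric
#'   with `metric = "suv"` liver statistics).
#' @param liver a [liver_ref()] (or list with `sulmean`/`sul_sd`, and
#'   `suvmean`/`suv_sd` for `metric = "suv"`).
#' @param multiplier floor multiplier, default 1.5.
#' @param metric which liver statistics define the floor: `"sul"` (default)
#'   or `"suv"`.
#' @return logical vector.
#' @export
#' @examples
#' lr <- liver_ref(sulmean = 2.0, sul_sd = 0.25, suvmean = 2.5, suv_sd = 0.3)
#' measurable(3.75, lr)  # floor 1.5 * (2 + 0.5) = 3.75 -> TRUE
#' measurable(3.74, lr)  # FALSE
measurable <- function(lesion_sulpeak, liver, multiplier = 1.5,
                       metric = c("sul", "suv")) {
  floor_val <- liver_floor(liver, match.arg(metric), multiplier)
  !is.na(lesion_sulpeak) & .ge(lesion_sulpeak, floor_val)
}

#' Between-scan comparability of the liver reference
#'
#' Baseline and follow-up PET studies are comparable when the liver
#' reference mean differs by no more than `limit_pct` percent of the
#' baseline value; a difference strictly exceeding the limit flags the pair
#' non-comparable.
#'
#' @param liver_baseline,liver_followup [liver_ref()] objects (or lists with
#'   `suvmean`/`sulmean` fields).
#' @param metric which mean is compared: `"suvmean"` (default) or `"sulmean"`.
#' @param limit_pct tolerated percent difference, default 20.
#' @return logical scalar.
#' @export
#' @examples
#' b <- liver_ref(2.0, 0.2, 2.0); f <- liver_ref(2.4, 0.2, 2.4)
#' comparable(b, f)  # 20% drift -> still comparable
comparable <- function(liver_baseline, liver_followup,
                       metric = c("suvmean", "sulmean"), limit_pct = 20) {
  metric <- match.arg(metric)
  b <- liver_baseline[[metric]]
  f <- liver_followup[[metric]]
  if (is.null(b) || is.na(b) || is.null(f) || is.na(f))
    stop("liver reference ", metric, " missing")
  if (b <= 0) stop("baseline liver ", metric, " must be > 0")
  drift <- 100 * abs(f - b) / b
  .le(drift, limit_pct)
}

applicability_status <- function(status, reason = "") {
  if (status != "ok" && !nzchar(reason))
    stop("non-ok applicability status requires a reason")
  structure(list(status = status, reason = reason),
            class = "applicability_status")
}

# Criteria-specific eligibility for one patient's scan pair.
# lesions_base / lesions_follow: data.frames with the lesion-table schema.
assess_one <- function(criteria, lesions_base, lesions_follow,
                       liver_base, liver_follow,
                       comparability_metric = "suvmean",
                       limit_pct = 20, multiplier = 1.5) {
  if (nrow(lesions_base) == 0)
    stop("no baseline lesions for applicability assessment")
  # Comparability: the 20% liver-drift rule applies to the PERCIST family
  # only; EORTC classifies every patient.
  if (criteria != "eortc" &&
      !comparable(liver_base, liver_follow, comparability_metric, limit_pct))
    return(applicability_status("not_comparable",
      sprintf("liver %s differs by more than %g%% between scans",
              comparability_metric, limit_pct)))
  # Measurability at baseline on the rule set's own metric.
  meas <- switch(criteria,
    percist10 = measurable(lesions_base$sulpeak, liver_base, multiplier, "sul"),
    mpercist  = measurable(lesions_base$suvpeak, liver_base, multiplier, "suv"),
    percistmax = ,
    eortc = !is.na(lesions_base$suvmax) & lesions_base$suvmax > 0
  )
  if (!any(meas)) {
    metric_name <- switch(criteria, percist10 = "SULpeak", mpercist = "SUVpeak",
                          "SUVmax")
    return(applicability_status("not_available",
      sprintf("no baseline lesion with measurable %s", metric_name)))
  }
  applicability_status("ok")
}

#' Assess per-patient, per-criteria applicability
#'
#' Screens every patient's baseline/follow-up scan pair for each requested
#' rule set: the pair is `not_comparable` when the liver reference mean
#' drifts by more than `limit_pct` percent between scans (PERCIST family
#' only; EORTC is exempt), and `not_available` when no baseline lesion
#' clears the measurability floor on the rule set's own metric (SULpeak for
#' PERCIST 1.0, SUVpeak for mPERCIST; PERCISTmax and EORTC only require a
#' positive SUVmax).  `not_comparable` dominates `not_available`.
#'
#' @param lesions lesion table (see [simulate_cohort()] for the schema).
#' @param liver per-scan liver reference table with columns `patient_id`,
#'   `scan`, `liver_suvmean`, `liver_suv_sd`, `liver_sulmean`, `liver_sul_sd`.
#' @param criteria character vector of rule-set names.
#' @param comparability_metric liver mean used for the drift check,
#'   `"suvmean"` (default) or `"sulmean"`.
#' @param limit_pct drift limit in percent (default 20).
#' @param multiplier measurability floor multiplier (default 1.5).
#' @return data.frame with columns `patient_id`, `criteria`, `status`
#'   (`ok` / `not_available` / `not_comparable`) and `reason`.
#' @export
assess_applicability <- function(lesions, liver,
                                 criteria = c("percist10", "mpercist",
                                              "percistmax", "eortc"),
                                 comparability_metric = "suvmean",
                                 limit_pct = 20, multiplier = 1.5) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  check_lesion_schema(lesions)
  patients <- unique(lesions$patient_id)
  out <- vector("list", length(patients) * length(criteria))
  k <- 0L
  for (pid in patients) {
    lb <- lesions[lesions$patient_id == pid & lesions$scan == "baseline", ]
    lf <- lesions[lesions$patient_id == pid & lesions$scan == "followup", ]
    if (nrow(lb) == 0 || nrow(lf) == 0)
      stop("patient ", pid, " is missing a baseline or follow-up scan")
    liv_b <- liver_row(liver, pid, "baseline")
    liv_f <- liver_row(liver, pid, "followup")
    for (cr in criteria) {
      st <- assess_one(cr, lb, lf, liv_b, liv_f,
                       comparability_metric, limit_pct, multiplier)
      k <- k + 1L
      out[[k]] <- data.frame(patient_id = pid, criteria = cr,
                             status = st$status, reason = st$reason,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

liver_row <- function(liver, pid, scan) {
  r <- liver[liver$patient_id == pid & liver$scan == scan, ]
  if (nrow(r) != 1)
    stop("expected exactly one liver reference row for patient ", pid,
         " scan ", scan)
  liver_ref(sulmean = r$liver_sulmean, sul_sd = r$liver_sul_sd,
            suvmean = r$liver_suvmean, suv_sd = r$liver_suv_sd)
}

lesion_table_columns <- c("patient_id", "scan", "lesion_id", "compartment",
                          "suvmax", "suvmean", "suvpeak", "sulpeak",
                          "mtv_cm3", "longest_diameter_mm", "is_new")

check_lesion_schema <- function(lesions) {
  missing_cols <- setdiff(lesion_table_columns, names(lesions))
  if (length(missing_cols))
    stop("lesion table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!all(lesions$scan %in% c("baseline", "followup")))
    stop("lesion table 'scan' must be 'baseline' or 'followup'")
  invisible(TRUE)
}
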