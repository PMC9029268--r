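#' Classify a longitudinal lesion cohort under metabolic response criteria
#'
#' The package's central function.  For every patient with a
#' baseline/follow-up scan pair it screens applicability (measurability
#' floor and liver-reference comparability), selects target lesions under
#' the requested convention, applies the rule sets and collapses the
#' four-level category into the disease-control (DC) versus progressive
#' disease (PD) dichotomy.
#'
#' @param lesions lesion table: one row per patient, scan
#'   (`baseline`/`followup`) and lesion, with columns `patient_id`, `scan`,
#'   `lesion_id`, `compartment`, `suvmax`, `suvmean`, `suvpeak`, `sulpeak`,
#'   `mtv_cm3`, `longest_diameter_mm`, `is_new`.
#' @param liver per-scan liver reference table (`patient_id`, `scan`,
#'   `liver_suvmean`, `liver_suv_sd`, `liver_sulmean`, `liver_sul_sd`).
#' @param criteria rule sets to apply (any of `"percist10"`, `"mpercist"`,
#'   `"percistmax"`, `"eortc"`).
#' @param selection target selection: `"hottest"`, `"all"`, or both.
#' @param comparability_metric liver mean for the 20% drift rule
#'   (`"suvmean"` or `"sulmean"`).
#' @param limit_pct liver drift limit in percent (default 20).
#' @param multiplier measurability floor multiplier (default 1.5).
#' @param overrides named list of [criteria_spec()] threshold overrides,
#'   keyed by criteria name.
#' @return object of class `pet_response`: list with `results` (one row per
#'   patient x criteria x selection: `patient_id`, `criteria`, `selection`,
#'   `status`, `reason`, `category`, `dichotomy`, `percent_change`,
#'   `target_baseline`, `target_followup`, `new_lesion`, `size_change_pct`)
#'   and `counts` (category tallies per criteria x selection).
#' @seealso [summary.pet_response()], [compare_survival()],
#'   [simulate_cohort()]
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 10, seed = 1))
#' fit <- pet_response(cohort$lesions, cohort$liver)
#' summary(fit)
pet_response <- function(lesions, liver,
                         criteria = c("percist10", "mpercist", "percistmax",
                                      "eortc"),
                         selection = "hottest",
                         comparability_metric = c("suvmean", "sulmean"),
                         limit_pct = 20, multiplier = 1.5,
                         overrides = list()) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  selection <- match.arg(selection, c("hottest", "all"), several.ok = TRUE)
  comparability_metric <- match.arg(comparability_metric)
  check_lesion_schema(lesions)
  key <- paste(lesions$patient_id, lesions$scan, lesions$lesion_id)
  if (anyDuplicated(key))
    stop("duplicate patient/scan/lesion rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))

  patients <- unique(lesions$patient_id)
  rows <- list()
  for (pid in patients) {
    lb <- lesions[lesions$patient_id == pid & lesions$scan == "baseline", ]
    lf <- lesions[lesions$patient_id == pid & lesions$scan == "followup", ]
    if (nrow(lb) == 0 || nrow(lf) == 0)
      stop("patient ", pid, " is missing a baseline or follow-up scan")
    liv_b <- liver_row(liver, pid, "baseline")
    liv_f <- liver_row(liver, pid, "followup")
    for (cr in criteria) {
      spec <- do.call(criteria_spec, c(list(cr), overrides[[cr]]))
      st <- assess_one(cr, lb, lf, liv_b, liv_f,
                       comparability_metric, limit_pct, multiplier)
      for (sel in selection) {
        if (st$status != "ok") {
          rows[[length(rows) + 1L]] <- response_row(pid, cr, sel, st)
          next
        }
        rows[[length(rows) + 1L]] <-
          classify_patient(pid, spec, sel, lb, lf, liv_b, liv_f,
                           multiplier, st)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results,
                 counts = tally_counts(results),
                 criteria = criteria, selection = selection,
                 settings = list(comparability_metric = comparability_metric,
                                 limit_pct = limit_pct,
                                 multiplier = multiplier,
                                 overrides = overrides)),
            class = "pet_response")
}

response_row <- function(pid, cr, sel, st, category = NA_character_,
                         pct = NA_real_, base = NA_real_, follow = NA_real_,
                         new_lesion = NA, size = NA_real_) {
  data.frame(patient_id = pid, criteria = cr, selection = sel,
             status = st$status, reason = st$reason,
             category = category,
             dichotomy = if (is.na(category)) NA_character_
                         else as.character(dichotomize(category)),
             percent_change = pct, target_baseline = base,
             target_followup = follow, new_lesion = new_lesion,
             size_change_pct = size, stringsAsFactors = FALSE)
}

classify_patient <- function(pid, spec, sel, lb, lf, liv_b, liv_f,
                             multiplier, st) {
  metric <- spec$metric
  cand <- switch(spec$name,
    percist10 = measurable(lb$sulpeak, liv_b, multiplier, "sul"),
    mpercist  = measurable(lb$suvpeak, liv_b, multiplier, "suv"),
    !is.na(lb$suvmax) & lb$suvmax > 0)
  tgt <- select_target(lb, lf, metric, sel, spec$name, cand)
  pct <- percent_change(tgt$base, tgt$follow)
  new_lesion <- any(as.logical(lf$is_new))
  size <- target_size_change(lb, lf)
  background <- if (metric == "sulpeak") liv_f$sulmean else liv_f$suvmean
  lf_old <- lf[!as.logical(lf$is_new), , drop = FALSE]
  all_resolved <- nrow(lf_old) > 0 &&
    all(.le(lf_old[[metric]], background)) && !new_lesion
  category <- if (spec$name == "eortc") {
    classify_eortc(tgt$base, tgt$follow, new_lesion, size,
                   all_resolved = all_resolved, spec = spec)
  } else {
    classify_percist_family(spec, tgt$base, tgt$follow, new_lesion, size,
                            all_resolved = all_resolved)
  }
  response_row(pid, spec$name, sel, st, as.character(category), pct,
               tgt$base, tgt$follow, new_lesion, size)
}

# Largest percent increase in longest diameter over lesions present (and
# sized) at both scans; new lesions are excluded (they have their own rule).
target_size_change <- function(lb, lf) {
  lf <- lf[!as.logical(lf$is_new), , drop = FALSE]
  ids <- intersect(lb$lesion_id, lf$lesion_id)
  b <- lb$longest_diameter_mm[match(ids, lb$lesion_id)]
  f <- lf$longest_diameter_mm[match(ids, lf$lesion_id)]
  ok <- !is.na(b) & !is.na(f) & b > 0
  if (!any(ok)) return(NA_real_)
  max(100 * (f[ok] - b[ok]) / b[ok])
}

tally_counts <- function(results) {
  out <- list()
  for (cr in unique(results$criteria)) {
    for (sel in unique(results$selection)) {
      r <- results[results$criteria == cr & results$selection == sel, ]
      cat_tab <- table(factor(r$category, levels = response_levels))
      out[[length(out) + 1L]] <- data.frame(
        criteria = cr, selection = sel,
        n = nrow(r), classified = sum(r$status == "ok"),
        not_available = sum(r$status == "not_available"),
        not_comparable = sum(r$status == "not_comparable"),
        CMR = unname(cat_tab["CMR"]), PMR = unname(cat_tab["PMR"]),
        SMD = unname(cat_tab["SMD"]), PMD = unname(cat_tab["PMD"]),
        DC = sum(r$dichotomy == "DC", na.rm = TRUE),
        PD = sum(r$dichotomy == "PD", na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.pet_response <- function(x, ...) {
  cat("Metabolic response classification:",
      length(unique(x$results$patient_id)), "patients,",
      paste(vapply(x$criteria, criteria_label, ""), collapse = ", "),
      "\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Summarize a metabolic response classification
#'
#' @param object a [pet_response()] object.
#' @param ... unused.
#' @return the per-criteria count table (category tallies, DC/PD split and
#'   exclusion counts), invisibly returned after printing.
#' @export
summary.pet_response <- function(object, ...) {
  cat("Patients:", length(unique(object$results$patient_id)), "\n")
  cat("Comparability metric:", object$settings$comparability_metric,
      "| liver drift limit:", object$settings$limit_pct,
      "% | measurability multiplier:", object$settings$multiplier, "\n\n")
  for (i in seq_len(nrow(object$counts))) {
    co <- object$counts[i, ]
    cat(sprintf("%-12s %-8s DC %d/%d, PD %d (CMR %d, PMR %d, SMD %d, PMD %d; n.a. %d, n.c. %d)\n",
                criteria_label(co$criteria), co$selection,
                co$DC, co$classified, co$PD,
                co$CMR, co$PMR, co$SMD, co$PMD,
                co$not_available, co$not_comparable))
  }
  invisible(object$counts)
}

#' @export
as.data.frame.pet_response <- function(x, ...) x$results
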