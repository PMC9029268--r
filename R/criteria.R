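#' Rule-set specification for a metabolic response criteria system
#'
#' Builds the threshold table for one of the four supported rule sets:
#' PERCIST 1.0 (SULpeak), mPERCIST (SUVpeak), PERCISTmax (SUVmax) and
#' EORTC (SUVmax).  The PERCIST family declares progression at a +30%
#' uptake increase that is also at least 0.8 units in absolute terms,
#' response at a -30% decrease (PERCIST 1.0 additionally requires an
#' absolute decrease of 0.8 SUL units), and size progression at +30%.
#' EORTC uses +/-25% on SUVmax and a strict >20% increase in longest
#' diameter.
#'
#' @param name one of `"percist10"`, `"mpercist"`, `"percistmax"`, `"eortc"`.
#' @param ... optional overrides for individual threshold fields
#'   (`pmd_pct`, `pmr_pct`, `abs_unit_floor`, `pmr_abs_floor`,
#'   `size_pmd_pct`); values must be positive.
#' @return an object of class `criteria_spec`: a list with fields `name`,
#'   `metric` (`sulpeak`, `suvpeak` or `suvmax`), `pmd_pct`, `pmr_pct`,
#'   `abs_unit_floor` (NA for EORTC), `pmr_abs_floor` (NA except
#'   PERCIST 1.0), `size_pmd_pct` and `size_strict` (TRUE for EORTC's
#'   strictly-greater diameter rule).
#' @export
#' @examples
#' criteria_spec("percist10")
#' criteria_spec("eortc")
criteria_spec <- function(name = c("percist10", "mpercist", "percistmax", "eortc"),
                          ...) {
  name <- match.arg(name)
  spec <- switch(name,
    percist10  = list(name = name, metric = "sulpeak", pmd_pct = 30, pmr_pct = 30,
                      abs_unit_floor = 0.8, pmr_abs_floor = 0.8,
                      size_pmd_pct = 30, size_strict = FALSE),
    mpercist   = list(name = name, metric = "suvpeak", pmd_pct = 30, pmr_pct = 30,
                      abs_unit_floor = 0.8, pmr_abs_floor = NA_real_,
                      size_pmd_pct = 30, size_strict = FALSE),
    percistmax = list(name = name, metric = "suvmax", pmd_pct = 30, pmr_pct = 30,
                      abs_unit_floor = 0.8, pmr_abs_floor = NA_real_,
                      size_pmd_pct = 30, size_strict = FALSE),
    eortc      = list(name = name, metric = "suvmax", pmd_pct = 25, pmr_pct = 25,
                      abs_unit_floor = NA_real_, pmr_abs_floor = NA_real_,
                      size_pmd_pct = 20, size_strict = TRUE)
  )
  dots <- list(...)
  bad <- setdiff(names(dots),
                 c("pmd_pct", "pmr_pct", "abs_unit_floor", "pmr_abs_floor",
                   "size_pmd_pct"))
  if (length(bad))
    stop("unknown criteria_spec override(s): ", paste(bad, collapse = ", "))
  for (nm in names(dots)) {
    v <- dots[[nm]]
    if (!is.na(v) && v <= 0) stop("criteria_spec override '", nm, "' must be > 0")
    spec[[nm]] <- v
  }
  structure(spec, class = "criteria_spec")
}

#' @export
print.criteria_spec <- function(x, ...) {
  cat("<criteria_spec> ", criteria_label(x$name), " (metric: ", x$metric, ")\n",
      sep = "")
  cat("  PMD: uptake >= +", x$pmd_pct, "%", sep = "")
  if (!is.na(x$abs_unit_floor))
    cat(" and absolute increase >= ", x$abs_unit_floor, " units", sep = "")
  cat("; size ", if (x$size_strict) "> +" else ">= +", x$size_pmd_pct,
      "%; or new lesion\n", sep = "")
  cat("  PMR: uptake <= -", x$pmr_pct, "%", sep = "")
  if (!is.na(x$pmr_abs_floor))
    cat(" and absolute decrease >= ", x$pmr_abs_floor, " units", sep = "")
  cat("\n")
  invisible(x)
}

criteria_label <- function(name) {
  c(percist10 = "PERCIST 1.0", mpercist = "mPERCIST",
    percistmax = "PERCISTmax", eortc = "EORTC")[[name]]
}

# Comparison tolerance for printed rule constants.  Percent changes handed to
# the classifier are usually reconstructed from uptake values (follow/base),
# so an input meant to sit exactly on a printed boundary like 30% can land a
# few ulps off it; boundary comparisons therefore carry a small absolute slack.
.rule_eps <- 1e-8
.ge <- function(a, b) a >= b - .rule_eps
.le <- function(a, b) a <= b + .rule_eps
.gt <- function(a, b) a > b + .rule_eps

response_levels <- c("CMR", "PMR", "SMD", "PMD")

#' Percent change between baseline and follow-up
#'
#' @param baseline_value,followup_value numeric vectors; baseline must be
#'   strictly positive.
#' @return `100 * (followup - baseline) / baseline`.
#' @export
#' @examples
#' percent_change(5, 7)   # +40
#' percent_change(4, 2)   # -50
percent_change <- function(baseline_value, followup_value) {
  if (any(!is.finite(baseline_value)) || any(baseline_value <= 0))
    stop("baseline_value must be finite and > 0")
  100 * (followup_value - baseline_value) / baseline_value
}

resolve_resolved <- function(followup_value, background_level, all_resolved, n) {
  if (!is.null(all_resolved)) return(rep_len(as.logical(all_resolved), n))
  if (is.null(background_level) || all(is.na(background_level)))
    return(rep_len(FALSE, n))
  .le(followup_value, rep_len(background_level, n))
}

#' Classify a PERCIST-family response
#'
#' Applies the PERCIST progression/response rules to baseline and follow-up
#' target-lesion uptake on the rule set's own metric.  Progressive metabolic
#' disease (PMD) requires an uptake increase of at least `pmd_pct` percent
#' that is also at least `abs_unit_floor` in absolute units, OR target-lesion
#' size progression, OR a new FDG-avid lesion; complete metabolic response
#' (CMR) requires all lesions resolved to background; partial metabolic
#' response (PMR) requires a decrease of at least `pmr_pct` percent (for
#' PERCIST 1.0 also an absolute decrease of at least 0.8 SUL units);
#' otherwise stable metabolic disease (SMD).  Precedence: PMD > CMR > PMR >
#' SMD.  All arguments are vectorized.
#'
#' @param spec a [criteria_spec()] from the PERCIST family.
#' @param base_val,follow_val target-lesion uptake on `spec$metric`.
#' @param new_lesions logical: any new FDG-avid lesion at follow-up.
#' @param target_size_change_pct percent change in target-lesion size
#'   (longest diameter); `NA` is treated as no size information.
#' @param background_level background uptake (typically the liver reference
#'   mean on the same metric) against which complete resolution is judged;
#'   ignored when `all_resolved` is given.
#' @param all_resolved optional logical: all of the patient's lesions are
#'   resolved to background (the CMR condition assessed over every lesion,
#'   not just the target).
#' @return factor with levels `CMR`, `PMR`, `SMD`, `PMD`.
#' @export
#' @examples
#' sp <- criteria_spec("percist10")
#' classify_percist_family(sp, 5, 7)          # +40%, +2.0 -> PMD
#' classify_percist_family(sp, 2, 2.7)        # +35% but +0.7 < 0.8 -> SMD
#' classify_percist_family(sp, 5, 3)          # -40%, -2.0 -> PMR
classify_percist_family <- function(spec, base_val, follow_val,
                                    new_lesions = FALSE,
                                    target_size_change_pct = 0,
                                    background_level = NULL,
                                    all_resolved = NULL) {
  stopifnot(inherits(spec, "criteria_spec"))
  if (spec$name == "eortc")
    stop("spec is EORTC; use classify_eortc()")
  n <- max(length(base_val), length(follow_val), length(new_lesions),
           length(target_size_change_pct))
  base_val <- rep_len(base_val, n); follow_val <- rep_len(follow_val, n)
  new_lesions <- rep_len(as.logical(new_lesions), n)
  size <- rep_len(as.numeric(target_size_change_pct), n)
  size[is.na(size)] <- 0
  pct <- percent_change(base_val, follow_val)
  abs_chg <- follow_val - base_val

  pmd_uptake <- .ge(pct, spec$pmd_pct) & .ge(abs_chg, spec$abs_unit_floor)
  pmd_size <- if (spec$size_strict) .gt(size, spec$size_pmd_pct)
              else .ge(size, spec$size_pmd_pct)
  pmd <- pmd_uptake | pmd_size | new_lesions

  resolved <- resolve_resolved(follow_val, background_level, all_resolved, n)

  pmr <- .le(pct, -spec$pmr_pct)
  if (!is.na(spec$pmr_abs_floor))
    pmr <- pmr & .le(abs_chg, -spec$pmr_abs_floor)

  out <- rep("SMD", n)
  out[pmr] <- "PMR"
  out[resolved] <- "CMR"
  out[pmd] <- "PMD"
  factor(out, levels = response_levels)
}

#' Classify an EORTC metabolic response
#'
#' EORTC rules on SUVmax: PMD at an increase of at least 25% OR a strict
#' >20% increase in the lesion's longest diameter OR a new lesion; CMR when
#' all lesions are indistinguishable from background; PMR at a decrease of
#' at least 25%; otherwise SMD.  Precedence: PMD > CMR > PMR > SMD.
#'
#' @param base_suvmax,follow_suvmax target-lesion SUVmax at baseline and
#'   follow-up.
#' @param new_lesions logical: any new FDG-avid lesion at follow-up.
#' @param longest_diameter_change_pct percent change in longest diameter;
#'   `NA` (unknown) classifies on uptake alone with a warning.
#' @param background_level,all_resolved see [classify_percist_family()].
#' @param spec optional [criteria_spec()] (defaults to `"eortc"`); allows
#'   threshold overrides.
#' @return factor with levels `CMR`, `PMR`, `SMD`, `PMD`.
#' @export
#' @examples
#' classify_eortc(6, 7.5)   # +25% -> PMD (inclusive boundary)
#' classify_eortc(6, 4.5)   # -25% -> PMR
#' classify_eortc(6, 6.6, longest_diameter_change_pct = 30)  # size -> PMD
classify_eortc <- function(base_suvmax, follow_suvmax, new_lesions = FALSE,
                           longest_diameter_change_pct = 0,
                           background_level = NULL, all_resolved = NULL,
                           spec = criteria_spec("eortc")) {
  stopifnot(inherits(spec, "criteria_spec"))
  n <- max(length(base_suvmax), length(follow_suvmax), length(new_lesions),
           length(longest_diameter_change_pct))
  base_suvmax <- rep_len(base_suvmax, n)
  follow_suvmax <- rep_len(follow_suvmax, n)
  new_lesions <- rep_len(as.logical(new_lesions), n)
  size <- rep_len(as.numeric(longest_diameter_change_pct), n)
  if (anyNA(size)) {
    warning("longest diameter change unavailable; classifying on uptake alone")
    size[is.na(size)] <- 0
  }
  pct <- percent_change(base_suvmax, follow_suvmax)
  pmd <- .ge(pct, spec$pmd_pct) |
    (if (spec$size_strict) .gt(size, spec$size_pmd_pct)
     else .ge(size, spec$size_pmd_pct)) |
    new_lesions
  resolved <- resolve_resolved(follow_suvmax, background_level, all_resolved, n)
  pmr <- .le(pct, -spec$pmr_pct)

  out <- rep("SMD", n)
  out[pmr] <- "PMR"
  out[resolved] <- "CMR"
  out[pmd] <- "PMD"
  factor(out, levels = response_levels)
}

#' Collapse a response category into the disease-control dichotomy
#'
#' CMR, PMR and SMD count as disease control (DC); PMD counts as
#' progressive disease (PD).
#'
#' @param category character or factor of categories `CMR`/`PMR`/`SMD`/`PMD`.
#' @return factor with levels `DC`, `PD`.
#' @export
#' @examples
#' dichotomize(c("CMR", "SMD", "PMD"))
dichotomize <- function(category) {
  category <- as.character(category)
  ok <- category %in% response_levels
  if (any(!ok & !is.na(category)))
    stop("invalid response category: ",
         paste(unique(category[!ok]), collapse = ", "))
  factor(ifelse(category == "PMD", "PD", "DC"), levels = c("DC", "PD"))
}
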