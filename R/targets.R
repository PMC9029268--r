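#' Select target-lesion uptake values for a scan pair
#'
#' Implements the two target-selection conventions.  `mode = "hottest"`:
#' the PERCIST family compares the hottest lesion of each scan
#' independently (the target need not be the same lesion at baseline and
#' follow-up), whereas EORTC tracks the baseline-hottest lesion and uses
#' that same lesion's follow-up value.  `mode = "all"`: one index lesion
#' per compartment (the compartment-hottest) is selected and the metric is
#' summed over index lesions — per scan independently for the PERCIST
#' family, baseline-selected and tracked forward for EORTC.  New follow-up
#' lesions never enter the uptake comparison (they trigger progression via
#' the new-lesion rule instead).  Ties for "hottest" are broken by larger
#' MTV, then by lexicographic lesion id.
#'
#' @param lesions_baseline,lesions_followup data.frames with columns
#'   `lesion_id`, `compartment`, the metric column, `mtv_cm3` and (for the
#'   follow-up) `is_new`.
#' @param metric column name of the uptake metric (`sulpeak`, `suvpeak`,
#'   `suvmax`).
#' @param mode `"hottest"` or `"all"`.
#' @param criteria rule-set name; decides between per-scan selection
#'   (PERCIST family) and baseline-tracked selection (EORTC).
#' @param candidates_baseline optional logical vector marking which
#'   baseline lesions are measurable (defaults to all).
#' @return list with `base`, `follow` (numeric target values), and
#'   `base_ids`, `follow_ids` (lesion ids entering each value).
#' @export
#' @examples
#' b <- data.frame(lesion_id = c("A", "B"), compartment = "lung",
#'                 suvmax = c(8, 5), mtv_cm3 = c(2, 2))
#' f <- data.frame(lesion_id = c("A", "B"), compartment = "lung",
#'                 suvmax = c(4, 6), mtv_cm3 = c(2, 2), is_new = FALSE)
#' select_target(b, f, "suvmax", "hottest", "percistmax")$follow  # 6 (B)
#' select_target(b, f, "suvmax", "hottest", "eortc")$follow       # 4 (A)
select_target <- function(lesions_baseline, lesions_followup, metric,
                          mode = c("hottest", "all"),
                          criteria = c("percist10", "mpercist", "percistmax",
                                       "eortc"),
                          candidates_baseline = NULL) {
  mode <- match.arg(mode)
  criteria <- match.arg(criteria)
  if (!metric %in% names(lesions_baseline))
    stop("metric column '", metric, "' not found in baseline lesions")
  lb <- lesions_baseline
  lf <- lesions_followup
  if ("is_new" %in% names(lf)) lf <- lf[!as.logical(lf$is_new), , drop = FALSE]
  if (is.null(candidates_baseline)) candidates_baseline <- rep(TRUE, nrow(lb))
  lb <- lb[candidates_baseline & !is.na(lb[[metric]]), , drop = FALSE]
  if (nrow(lb) == 0) stop("no measurable baseline lesion to select a target from")
  if (nrow(lf) == 0) stop("no follow-up lesions to select a target from")

  if (mode == "hottest") {
    b_id <- hottest_id(lb, metric)
    if (criteria == "eortc") {
      f_row <- lf[lf$lesion_id == b_id, , drop = FALSE]
      if (nrow(f_row) == 0)
        stop("baseline target lesion '", b_id, "' absent at follow-up")
      list(base = lb[[metric]][lb$lesion_id == b_id][1],
           follow = f_row[[metric]][1],
           base_ids = b_id, follow_ids = b_id)
    } else {
      f_id <- hottest_id(lf, metric)
      list(base = lb[[metric]][lb$lesion_id == b_id][1],
           follow = lf[[metric]][lf$lesion_id == f_id][1],
           base_ids = b_id, follow_ids = f_id)
    }
  } else {
    # one index lesion per compartment, metric summed over index lesions
    b_ids <- vapply(split(lb, lb$compartment), hottest_id, "", metric = metric)
    if (criteria == "eortc") {
      f_rows <- lf[lf$lesion_id %in% b_ids, , drop = FALSE]
      if (nrow(f_rows) == 0)
        stop("no baseline index lesion present at follow-up")
      list(base = sum(lb[[metric]][lb$lesion_id %in% b_ids]),
           follow = sum(f_rows[[metric]]),
           base_ids = unname(b_ids), follow_ids = f_rows$lesion_id)
    } else {
      f_ids <- vapply(split(lf, lf$compartment), hottest_id, "", metric = metric)
      list(base = sum(lb[[metric]][lb$lesion_id %in% b_ids]),
           follow = sum(lf[[metric]][lf$lesion_id %in% f_ids]),
           base_ids = unname(b_ids), follow_ids = unname(f_ids))
    }
  }
}

# deterministic hottest-lesion choice: metric, then MTV, then lesion id
hottest_id <- function(df, metric) {
  mtv <- if ("mtv_cm3" %in% names(df)) df$mtv_cm3 else rep(0, nrow(df))
  ord <- order(-df[[metric]], -mtv, as.character(df$lesion_id))
  as.character(df$lesion_id[ord[1]])
}
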