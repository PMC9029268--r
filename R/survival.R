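#' Kaplan-Meier product-limit estimate
#'
#' Fits the product-limit estimator (via `survival::survfit`) and reports
#' the step function and the median survival time, defined as the smallest
#' observed time at which the survival probability drops to 0.5 or below;
#' when the curve never reaches 0.5 the median is "not reached" (`NA`).
#'
#' @param records data.frame with columns `time_months` and `event`
#'   (logical/0-1), or a numeric vector of times (then `event` must be
#'   given).
#' @param event optional event indicator when `records` is a vector.
#' @return object of class `km_estimate`: list with `time`, `surv`
#'   (step function evaluated at the observed event/censoring times,
#'   starting implicitly at S(0) = 1), `n`, `n_events` and `median_months`
#'   (`NA` = not reached).
#' @export
#' @examples
#' km <- km_estimate(data.frame(time_months = c(1, 2, 3, 4),
#'                              event = c(TRUE, TRUE, FALSE, TRUE)))
#' km$median_months  # 2
km_estimate <- function(records, event = NULL) {
  if (is.data.frame(records)) {
    time <- records$time_months
    event <- records$event
  } else {
    time <- records
  }
  if (length(time) == 0) stop("no survival records")
  if (is.null(event) || length(event) != length(time))
    stop("event indicator must accompany every time")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "none")
  surv <- fit$surv
  med <- if (any(surv <= 0.5 + 1e-12)) min(fit$time[surv <= 0.5 + 1e-12])
         else NA_real_
  structure(list(time = fit$time, surv = surv, n = length(time),
                 n_events = sum(as.logical(event)), median_months = med),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate: n =", x$n, ", events =", x$n_events,
      ", median =",
      if (is.na(x$median_months)) "not reached"
      else paste(signif(x$median_months, 4), "months"), "\n")
  invisible(x)
}

#' @export
plot.km_estimate <- function(x, xlab = "Months", ylab = "Survival probability",
                             ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlim = c(0, max(x$time)), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# Log-rank chi-square statistic (observed-minus-expected form with
# hypergeometric variance), written for repeated evaluation under label
# permutation: the time ordering and event structure are computed once.
logrank_setup <- function(time, event) {
  ord <- order(time)
  ts <- time[ord]; ev <- as.logical(event)[ord]
  ev_times <- unique(ts[ev])
  first_pos <- match(ev_times, ts)              # n at risk = n - pos + 1
  ev_idx <- which(ev)
  ev_grp <- match(ts[ev_idx], ev_times)
  nj <- length(ts) - first_pos + 1
  dj <- as.numeric(rowsum(rep(1, length(ev_idx)), ev_grp))
  list(ord = ord, ev_times = ev_times, first_pos = first_pos,
       ev_idx = ev_idx, ev_grp = ev_grp, nj = nj, dj = dj)
}

logrank_chisq_from_setup <- function(setup, g) {
  gs <- g[setup$ord]
  n1 <- rev(cumsum(rev(gs)))[setup$first_pos]
  d1 <- as.numeric(rowsum(as.numeric(gs[setup$ev_idx]), setup$ev_grp))
  e1 <- setup$dj * n1 / setup$nj
  v1 <- ifelse(setup$nj > 1,
               setup$dj * (n1 / setup$nj) * (1 - n1 / setup$nj) *
                 (setup$nj - setup$dj) / (setup$nj - 1),
               0)
  U <- sum(d1 - e1); V <- sum(v1)
  if (V <= 0) 0 else U^2 / V
}

#' Monte-Carlo permutation log-rank test
#'
#' Compares the survival of two groups with the log-rank statistic
#' (observed minus expected events, hypergeometric variance), referring it
#' to its permutation distribution over random relabelings of group
#' membership rather than the asymptotic chi-square.  The p-value uses the
#' add-one correction `p = (1 + #permuted >= observed) / (1 + n_perm)`.
#'
#' @param group_a,group_b data.frames with `time_months` and `event`.
#' @param n_perm number of Monte-Carlo permutations (default 5000).
#' @param seed RNG seed.
#' @return the p-value, with attributes `statistic` (observed chi-square)
#'   and `n_perm`.
#' @export
logrank_permutation <- function(group_a, group_b, n_perm = 5000, seed = 1) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0)
    stop("both groups must be non-empty")
  time <- c(group_a$time_months, group_b$time_months)
  event <- c(group_a$event, group_b$event)
  g <- c(rep(1, nrow(group_a)), rep(0, nrow(group_b)))
  setup <- logrank_setup(time, event)
  obs <- logrank_chisq_from_setup(setup, g)
  set.seed(seed)
  n <- length(g)
  perm <- vapply(seq_len(n_perm), function(b) {
    logrank_chisq_from_setup(setup, g[sample.int(n)])
  }, 0)
  p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
  structure(p, statistic = obs, n_perm = n_perm)
}

welch_t_stat <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / length(x) + vy / length(y)
  if (se2 <= 0) {
    if (mean(x) == mean(y)) return(0)
    return(Inf * sign(mean(x) - mean(y)))
  }
  (mean(x) - mean(y)) / sqrt(se2)
}

#' Bootstrap t-test for two means
#'
#' Two-sided bootstrap test of equal means using the studentized (Welch)
#' statistic under the shifted null: both samples are recentered to the
#' pooled mean, resampled with replacement within group, and the observed
#' statistic is referred to the bootstrap distribution of the recomputed
#' statistic, with the add-one correction.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param seed RNG seed.
#' @return the p-value, with attribute `statistic` (observed Welch t).
#' @export
bootstrap_t <- function(x, y, n_boot = 5000, seed = 1) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample must have at least 2 observations")
  t_obs <- welch_t_stat(x, y)
  if (t_obs == 0 && stats::var(x) == 0 && stats::var(y) == 0)
    return(structure(1, statistic = 0))
  m <- mean(c(x, y))
  xc <- x - mean(x) + m
  yc <- y - mean(y) + m
  set.seed(seed)
  nx <- length(x); ny <- length(y)
  tb <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    tb[b] <- welch_t_stat(xc[sample.int(nx, replace = TRUE)],
                          yc[sample.int(ny, replace = TRUE)])
  }
  p <- (1 + sum(abs(tb) >= abs(t_obs) - 1e-12)) / (1 + n_boot)
  structure(p, statistic = t_obs)
}

#' Extract the DC/PD grouping from a classification
#'
#' @param fit a [pet_response()] object.
#' @param criteria,selection which result column to use.
#' @return data.frame `patient_id`, `group` for patients with
#'   applicability status `ok`.
#' @export
response_groups <- function(fit, criteria = "percist10",
                            selection = "hottest") {
  stopifnot(inherits(fit, "pet_response"))
  r <- fit$results
  r <- r[r$criteria == criteria & r$selection == selection &
           r$status == "ok", ]
  data.frame(patient_id = r$patient_id, group = r$dichotomy,
             stringsAsFactors = FALSE)
}

#' Compare survival between disease-control and progressive-disease groups
#'
#' Kaplan-Meier estimates per group plus the Monte-Carlo permutation
#' log-rank test.
#'
#' @param records data.frame with `patient_id`, `time_months`, `event`,
#'   `group` (`DC`/`PD`), e.g. from [simulate_survival()].
#' @param n_perm permutations for the log-rank test.
#' @param seed RNG seed.
#' @return object of class `survival_comparison`: per-group sizes, KM
#'   estimates and medians, and the permutation log-rank p-value.
#' @export
compare_survival <- function(records, n_perm = 5000, seed = 1) {
  stopifnot(all(c("time_months", "event", "group") %in% names(records)))
  dc <- records[records$group == "DC", ]
  pd <- records[records$group == "PD", ]
  if (nrow(dc) == 0 || nrow(pd) == 0)
    stop("both DC and PD groups must be non-empty")
  km_dc <- km_estimate(dc); km_pd <- km_estimate(pd)
  p <- logrank_permutation(dc, pd, n_perm = n_perm, seed = seed)
  structure(list(n_dc = nrow(dc), n_pd = nrow(pd),
                 km_dc = km_dc, km_pd = km_pd,
                 median_dc = km_dc$median_months,
                 median_pd = km_pd$median_months,
                 p_value = as.numeric(p),
                 statistic = attr(p, "statistic"), n_perm = n_perm,
                 seed = seed),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  fmt_med <- function(m) if (is.na(m)) "not reached"
                         else paste(signif(m, 4), "months")
  cat("DC (n =", x$n_dc, "): median", fmt_med(x$median_dc), "\n")
  cat("PD (n =", x$n_pd, "): median", fmt_med(x$median_pd), "\n")
  cat("Permutation log-rank p =", signif(x$p_value, 3),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}

#' @export
plot.survival_comparison <- function(x, xlab = "Months",
                                     ylab = "Survival probability", ...) {
  tmax <- max(x$km_dc$time, x$km_pd$time)
  graphics::plot(stats::stepfun(x$km_dc$time, c(1, x$km_dc$surv)),
                 do.points = FALSE, xlim = c(0, tmax), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, col = "forestgreen",
                 main = "Disease control vs progressive disease", ...)
  graphics::lines(stats::stepfun(x$km_pd$time, c(1, x$km_pd$surv)),
                  do.points = FALSE, col = "firebrick")
  graphics::legend("topright", legend = c("DC", "PD"), lty = 1,
                   col = c("forestgreen", "firebrick"), bty = "n")
  invisible(x)
}

# Patient-level percent change of one metric: uptake metrics use the
# baseline-hottest lesion tracked to follow-up; volume metrics (MTV, TLG)
# use totals over the lesions present at baseline.
patient_metric_change <- function(lesions, pid, metric) {
  lb <- lesions[lesions$patient_id == pid & lesions$scan == "baseline", ]
  lf <- lesions[lesions$patient_id == pid & lesions$scan == "followup", ]
  lf <- lf[!as.logical(lf$is_new), , drop = FALSE]
  get <- function(df) {
    if (metric == "tlg") df$mtv_cm3 * df$suvmean else df[[metric]]
  }
  if (metric %in% c("mtv_cm3", "tlg")) {
    ids <- intersect(lb$lesion_id, lf$lesion_id)
    b <- sum(get(lb[lb$lesion_id %in% ids, , drop = FALSE]))
    f <- sum(get(lf[lf$lesion_id %in% ids, , drop = FALSE]))
  } else {
    vals <- get(lb)
    id <- lb$lesion_id[order(-vals, as.character(lb$lesion_id))][1]
    b <- get(lb)[lb$lesion_id == id][1]
    f <- get(lf)[lf$lesion_id == id][1]
  }
  if (length(b) == 0 || length(f) == 0 || is.na(b) || b <= 0)
    return(NA_real_)
  100 * (f - b) / b
}

#' Per-group mean changes of PET parameters
#'
#' Summarizes, for the DC and PD groups, the mean and SD of the percent
#' change of each requested PET parameter, with a bootstrap t-test per
#' parameter — the per-group effect-size table of a response analysis.
#'
#' @param lesions lesion table (see [pet_response()]).
#' @param groups data.frame `patient_id`, `group` (e.g. from
#'   [response_groups()]).
#' @param metrics parameters to summarize; `"tlg"` is computed as
#'   MTV x SUVmean.
#' @param n_boot bootstrap resamples per test.
#' @param seed RNG seed.
#' @return data.frame: `metric`, `group`, `n`, `mean_change`, `sd_change`
#'   (NA, flagged in `note`, for groups of fewer than 2 patients) and
#'   `p_value` (same value on both group rows of a metric).
#' @export
summarize_changes <- function(lesions, groups,
                              metrics = c("suvpeak", "sulpeak", "suvmax",
                                          "mtv_cm3", "tlg"),
                              n_boot = 5000, seed = 1) {
  if (length(metrics) == 0)
    return(data.frame(metric = character(), group = character(),
                      n = integer(), mean_change = numeric(),
                      sd_change = numeric(), p_value = numeric(),
                      note = character()))
  out <- list()
  for (metric in metrics) {
    chg <- vapply(groups$patient_id, patient_metric_change, 0,
                  lesions = lesions, metric = metric)
    by_grp <- split(chg[!is.na(chg)], groups$group[!is.na(chg)])
    x <- by_grp[["DC"]]; y <- by_grp[["PD"]]
    p <- if (!is.null(x) && !is.null(y) && length(x) >= 2 && length(y) >= 2)
      as.numeric(bootstrap_t(x, y, n_boot = n_boot, seed = seed))
    else NA_real_
    for (grp in c("DC", "PD")) {
      v <- by_grp[[grp]]
      if (is.null(v)) v <- numeric(0)
      out[[length(out) + 1L]] <- data.frame(
        metric = metric, group = grp, n = length(v),
        mean_change = if (length(v)) mean(v) else NA_real_,
        sd_change = if (length(v) >= 2) stats::sd(v) else NA_real_,
        p_value = p,
        note = if (length(v) < 2) "fewer than 2 patients; SD undefined"
               else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
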