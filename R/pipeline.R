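#' Validate a lesion table
#'
#' Schema and sanity diagnostics for a lesion table: missing columns,
#' non-positive uptake values, duplicate patient/scan/lesion rows, and
#' orphan scans (a follow-up without a baseline or vice versa).
#'
#' @param table a data.frame, or a path to a CSV file.
#' @return data.frame of diagnostics (`rule`, `row`, `message`); zero rows
#'   for a well-formed table.
#' @export
validate_lesion_table <- function(table) {
  if (is.character(table)) {
    if (!file.exists(table)) stop("file not found: ", table)
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  }
  diags <- list()
  note <- function(rule, row, message)
    diags[[length(diags) + 1L]] <<- data.frame(rule = rule, row = row,
                                               message = message,
                                               stringsAsFactors = FALSE)
  missing_cols <- setdiff(lesion_table_columns, names(table))
  if (length(missing_cols)) {
    note("missing_column", NA_integer_,
         paste("missing column(s):", paste(missing_cols, collapse = ", ")))
    return(do.call(rbind, diags))
  }
  for (col in c("suvmax", "suvmean", "suvpeak")) {
    bad <- which(!is.na(table[[col]]) & table[[col]] <= 0)
    for (r in bad)
      note("non_positive_uptake", r,
           sprintf("row %d: %s = %g is not positive", r, col, table[[col]][r]))
  }
  key <- paste(table$patient_id, table$scan, table$lesion_id)
  for (r in which(duplicated(key)))
    note("duplicate_lesion", r, sprintf("row %d duplicates %s", r, key[r]))
  for (pid in unique(table$patient_id)) {
    scans <- unique(table$scan[table$patient_id == pid])
    if ("followup" %in% scans && !"baseline" %in% scans)
      note("orphan_scan", NA_integer_,
           sprintf("patient %s has a follow-up scan but no baseline", pid))
    if ("baseline" %in% scans && !"followup" %in% scans)
      note("orphan_scan", NA_integer_,
           sprintf("patient %s has a baseline scan but no follow-up", pid))
  }
  if (length(diags) == 0)
    return(data.frame(rule = character(), row = integer(),
                      message = character()))
  do.call(rbind, diags)
}

default_run_config <- function() {
  list(mode = "synthetic",
       criteria = c("percist10", "mpercist", "percistmax", "eortc"),
       selection = c("hottest", "all"),
       comparability_metric = "suvmean",
       limit_pct = 20, multiplier = 1.5,
       sul_method = "lbm_janmahasatian",
       cohort = list(), survival = list(), n_perm = 5000, seed = 42)
}

#' Run the full response-analysis pipeline
#'
#' Orchestrates generate (or load) -> screen -> classify -> compare as one
#' reproducible run: writes the lesion/liver/patient tables, the
#' applicability and classification tables, per-criteria category counts,
#' the per-group change summary, the survival comparison and a manifest
#' (configuration, thresholds, seed, package version).  Identical
#' configuration and seed produce byte-identical artifacts.
#'
#' @param config a named list (or path to a YAML file) overriding the
#'   defaults: `mode` (`"synthetic"` or `"table"`), `criteria`,
#'   `selection`, `comparability_metric`, `limit_pct`, `multiplier`,
#'   `cohort` ([cohort_config()] overrides, synthetic mode), `lesions_csv`
#'   / `liver_csv` / `survival_csv` (table mode), `survival` (hazard and
#'   censoring overrides), `n_perm`, `seed`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the classification (`fit`), the change
#'   summary, the survival comparison and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("petresp_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  created <- !dir.exists(out_dir)
  if (created) dir.create(out_dir, recursive = TRUE)
  on_fail <- function(e) {
    if (created) unlink(out_dir, recursive = TRUE)
    stop(e)
  }
  tryCatch({
    if (cfg$mode == "synthetic") {
      cc <- do.call(cohort_config,
                    utils::modifyList(list(seed = cfg$seed), cfg$cohort))
      cohort <- simulate_cohort(cc)
      lesions <- cohort$lesions; liver <- cohort$liver
      utils::write.csv(cohort$patients, file.path(out_dir, "patients.csv"),
                       row.names = FALSE)
      utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                       row.names = FALSE)
    } else if (cfg$mode == "table") {
      diags <- validate_lesion_table(cfg$lesions_csv)
      if (nrow(diags))
        stop("lesion table failed validation:\n",
             paste(diags$message, collapse = "\n"))
      lesions <- utils::read.csv(cfg$lesions_csv, stringsAsFactors = FALSE)
      liver <- utils::read.csv(cfg$liver_csv, stringsAsFactors = FALSE)
    } else stop("unknown mode: ", cfg$mode)
    utils::write.csv(lesions, file.path(out_dir, "lesions.csv"),
                     row.names = FALSE)
    utils::write.csv(liver, file.path(out_dir, "liver.csv"),
                     row.names = FALSE)

    appl <- assess_applicability(lesions, liver, cfg$criteria,
                                 cfg$comparability_metric, cfg$limit_pct,
                                 cfg$multiplier)
    utils::write.csv(appl, file.path(out_dir, "applicability.csv"),
                     row.names = FALSE)

    fit <- pet_response(lesions, liver, criteria = cfg$criteria,
                        selection = cfg$selection,
                        comparability_metric = cfg$comparability_metric,
                        limit_pct = cfg$limit_pct,
                        multiplier = cfg$multiplier)
    utils::write.csv(fit$results, file.path(out_dir, "classification.csv"),
                     row.names = FALSE)
    jsonlite::write_json(fit$counts, file.path(out_dir, "counts.json"),
                         dataframe = "rows", pretty = TRUE, digits = NA)

    groups <- response_groups(fit, cfg$criteria[1], cfg$selection[1])
    changes <- summarize_changes(lesions, groups, n_boot = min(cfg$n_perm, 2000),
                                 seed = cfg$seed)
    utils::write.csv(changes, file.path(out_dir, "changes_summary.csv"),
                     row.names = FALSE)

    surv_report <- NULL
    if (cfg$mode == "synthetic") {
      sv <- do.call(simulate_survival,
                    utils::modifyList(list(groups = groups,
                                           seed = cfg$seed + 1L),
                                      cfg$survival))
    } else if (!is.null(cfg$survival_csv)) {
      sv <- utils::read.csv(cfg$survival_csv, stringsAsFactors = FALSE)
      sv <- merge(sv, groups, by = "patient_id")
    } else sv <- NULL
    if (!is.null(sv) && length(unique(sv$group)) == 2) {
      utils::write.csv(sv, file.path(out_dir, "survival.csv"),
                       row.names = FALSE)
      cmp <- compare_survival(sv, n_perm = cfg$n_perm, seed = cfg$seed + 2L)
      surv_report <- list(criteria = cfg$criteria[1],
                          selection = cfg$selection[1],
                          n_dc = cmp$n_dc, n_pd = cmp$n_pd,
                          median_dc_months = cmp$median_dc,
                          median_pd_months = cmp$median_pd,
                          logrank_p = cmp$p_value, n_perm = cmp$n_perm,
                          seed = cfg$seed)
      jsonlite::write_json(surv_report, file.path(out_dir, "survival.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           na = "string")
      km_steps <- rbind(
        data.frame(group = "DC", time_months = cmp$km_dc$time,
                   survival = cmp$km_dc$surv),
        data.frame(group = "PD", time_months = cmp$km_pd$time,
                   survival = cmp$km_pd$surv))
      utils::write.csv(km_steps, file.path(out_dir, "km_curves.csv"),
                       row.names = FALSE)
    }

    cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
    manifest <- list(
      package = "petresp",
      version = as.character(utils::packageVersion("petresp")),
      seed = cfg$seed,
      config = cfg,
      thresholds = lapply(cfg$criteria, function(cr)
        unclass(criteria_spec(cr))),
      config_sha = substr(paste(as.integer(charToRaw(as.character(cfg_json))),
                                collapse = ""), 1, 40))
    # stable content fingerprint of the config
    tmp <- file.path(out_dir, "config.json")
    writeLines(as.character(cfg_json), tmp)
    manifest$config_sha <- unname(tools::md5sum(tmp))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(fit = fit, changes = changes, survival = surv_report,
                   manifest = manifest, out_dir = out_dir))
  }, error = on_fail)
}
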