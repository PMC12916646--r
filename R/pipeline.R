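# End-to-end orchestration: ingest -> dedup -> cohort filters -> 2x2
# tables -> four-algorithm signals -> consensus -> subgroups ->
# co-medication sensitivity -> time-to-onset, with a stage-by-stage
# manifest of record counts (flow conservation is a tested invariant).

#' Build a run configuration
#'
#' @param synonyms target-drug synonym list (generic and brand names).
#' @param indication_pts PTs describing the drug's own indications,
#'   excluded from the cohort's event lists.
#' @param sensitivity_drugs co-medications excluded report-wise in the
#'   sensitivity re-analysis.
#' @param subgroups named list of strata values analysed per demographic
#'   axis.
#' @param tto_clusters named list of PT vectors defining TTO strata.
#' @param drop_missing_demographics if TRUE, cohort reports missing age or
#'   sex are removed (strict reading of the cohort rules); the default
#'   keeps them as a `missing` stratum.
#' @param yates use the continuity-corrected chi-square.
#' @param ic_z normal multiplier for the IC interval (1.96; 2 for legacy
#'   two-SD bounds).
#' @param min_cases minimum case count for the frequentist criteria.
#' @return object of class `run_config`.
#' @export
run_config <- function(synonyms = TARGET_SYNONYMS,
                       indication_pts = character(),
                       sensitivity_drugs = c("PREDNISONE", "ASPIRIN",
                                             "HYDROXYCHLOROQUINE"),
                       subgroups = list(
                         sex = c("M", "F"),
                         age_group = c("<18", "18-64", ">=65"),
                         reporter = c("healthcare", "consumer")),
                       tto_clusters = default_tto_clusters(),
                       drop_missing_demographics = FALSE,
                       yates = FALSE, ic_z = 1.96, min_cases = 3L) {
  structure(list(synonyms = synonyms,
                 indication_pts = as.character(indication_pts),
                 sensitivity_drugs = as.character(sensitivity_drugs),
                 subgroups = subgroups, tto_clusters = tto_clusters,
                 drop_missing_demographics = isTRUE(drop_missing_demographics),
                 yates = isTRUE(yates), ic_z = ic_z,
                 min_cases = as.integer(min_cases)),
            class = "run_config")
}

#' Default bleeding / rash cluster membership
#'
#' SMQ-like term lists matching the synthetic vocabulary; for real data
#' supply curated lists in the run configuration.
#'
#' @return named list of PT vectors.
#' @export
default_tto_clusters <- function() {
  v <- pt_vocabulary()
  list(bleeding = v$pt[v$cluster == "bleeding"],
       rash = v$pt[v$cluster == "rash"])
}

#' Write / read a run configuration as YAML
#'
#' Configurations round-trip losslessly, which is what makes a run
#' reproducible from its manifest.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   the `run_config` object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

manifest_add <- function(manifest, stage, n, removed = 0L, reason = "") {
  rbind(manifest, data.frame(stage = stage, n_reports = n,
                             removed = removed, reason = reason,
                             stringsAsFactors = FALSE))
}

#' Run the full disproportionality and time-to-onset analysis
#'
#' Executes the whole study on one database: deduplication, cohort
#' selection, indication-PT exclusion, date audit, PT- and SOC-level
#' 2x2 tables with the four algorithms and consensus classification,
#' stratum-restricted subgroup re-analysis (the shrinkage prior is
#' re-fitted per stratum, each stratum being its own background),
#' co-medication sensitivity re-analysis, and parametric TTO modelling.
#' Deterministic given inputs and configuration.
#'
#' @param data an [srs_data()] object, or a directory of FAERS-dialect
#'   quarterly files.
#' @param config a [run_config()].
#' @param pt_soc_map PT-to-SOC map (data.frame `pt`, `soc`).
#' @param out_dir optional directory; when given, signal tables (TSV),
#'   the TTO report and a JSON manifest are written there.
#' @return object of class `pv_analysis`; see the elements `manifest`,
#'   `signals_pt`, `signals_soc`, `venn`, `subgroups`, `sensitivity`,
#'   `tto`, `demographics`, `config_hash`. If a stage empties the cohort
#'   the run stops early and returns the manifest explaining which.
#' @export
run_full_analysis <- function(data, config = run_config(),
                              pt_soc_map = pt_vocabulary(),
                              out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(data)) data <- read_faers_quarter(data)
  stopifnot(inherits(data, "srs_data"))
  hash <- config_hash(config)
  manifest <- data.frame(stage = character(), n_reports = integer(),
                         removed = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  manifest <- manifest_add(manifest, "raw", nrow(data$demo))

  dd <- deduplicate_reports(data)
  manifest <- manifest_add(manifest, "deduplicated", nrow(dd$demo),
                           dd$meta$duplicates_removed, "case_versions")

  target_ids <- target_report_ids(dd, config$synonyms)
  manifest <- manifest_add(manifest, "target_cohort", length(target_ids),
                           nrow(dd$demo) - length(target_ids),
                           "not_primary_suspect")
  empty_stop <- function(stage) {
    structure(list(manifest = manifest, config = config,
                   config_hash = hash, empty_at = stage),
              class = c("pv_analysis_empty", "pv_analysis"))
  }
  if (!length(target_ids)) return(empty_stop("target_cohort"))

  # indication-PT exclusion: cohort event lists only
  cohort <- subset_srs(dd, target_ids)
  cohort <- exclude_indication_pts(cohort, config$indication_pts)
  dropped_ind <- cohort$meta$reports_dropped_empty
  if (dropped_ind > 0) {
    dd <- subset_srs(dd, setdiff(dd$demo$primaryid,
                                 setdiff(target_ids,
                                         cohort$demo$primaryid)))
  }
  # splice the reduced cohort event lists back into the database
  dd$reac <- rbind(dd$reac[!(dd$reac$primaryid %in% target_ids), ,
                           drop = FALSE],
                   cohort$reac)
  target_ids <- cohort$demo$primaryid
  manifest <- manifest_add(manifest, "indication_excluded",
                           length(target_ids), dropped_ind,
                           "no_events_left")
  if (!length(target_ids)) return(empty_stop("indication_excluded"))

  audit <- audit_dates(cohort, config$synonyms)
  bad_ids <- audit$log$primaryid
  if (length(bad_ids)) {
    dd <- subset_srs(dd, setdiff(dd$demo$primaryid, bad_ids))
    target_ids <- setdiff(target_ids, bad_ids)
  }
  manifest <- manifest_add(manifest, "date_audit", length(target_ids),
                           length(bad_ids), "event_before_start")
  if (!length(target_ids)) return(empty_stop("date_audit"))

  tab <- build_event_table(dd, pt_soc_map, config$synonyms)
  if (config$drop_missing_demographics) {
    drop <- tab$reports$is_target &
      (tab$reports$sex == "missing" | tab$reports$age_group == "missing")
    drop_ids <- tab$reports$primaryid[drop]
    if (length(drop_ids)) {
      dd <- subset_srs(dd, setdiff(dd$demo$primaryid, drop_ids))
      target_ids <- setdiff(target_ids, drop_ids)
      tab <- build_event_table(dd, pt_soc_map, config$synonyms)
    }
    manifest <- manifest_add(manifest, "demographics", length(target_ids),
                             length(drop_ids), "missing_age_or_sex")
    if (!length(target_ids)) return(empty_stop("demographics"))
  }
  reports <- tab$reports
  events <- tab$events

  # --- main signal tables ----------------------------------------------
  opts <- function(tables, prior = NULL) {
    compute_signal_metrics(tables, prior = prior, yates = config$yates,
                           ic_z = config$ic_z,
                           min_cases = config$min_cases)
  }
  pt_tables <- build_contingency(reports, events, "pt", "all")
  soc_tables <- build_contingency(reports, events, "soc", "all")
  signals_pt <- opts(pt_tables)
  signals_soc <- opts(soc_tables)
  venn <- consensus_venn(signals_pt)

  # --- subgroups (stratum-restricted background, prior re-fitted) ------
  subgroups <- list()
  for (axis in names(config$subgroups)) {
    for (value in config$subgroups[[axis]]) {
      spec <- do.call(stratum_spec, stats::setNames(list(value), axis))
      strat_reports <- apply_stratum(reports, spec)
      tabs <- suppressWarnings(
        build_contingency(strat_reports, events, "pt", spec$label))
      subgroups[[spec$label]] <- if (nrow(tabs)) opts(tabs) else tabs
    }
  }

  # --- sensitivity ------------------------------------------------------
  sens_spec <- stratum_spec(exclude_drugs = config$sensitivity_drugs,
                            label = "sensitivity")
  sens_reports <- apply_stratum(reports, sens_spec, drug = dd$drug)
  sens_tables <- suppressWarnings(
    build_contingency(sens_reports, events, "pt", "sensitivity"))
  signals_sens <- if (nrow(sens_tables)) opts(sens_tables) else sens_tables
  sensitivity <- list(signals = signals_sens,
                      persistence = compare_runs(signals_pt, signals_sens))

  # --- time-to-onset ----------------------------------------------------
  cohort_clean <- subset_srs(dd, target_ids)
  tto_ex <- extract_tto(cohort_clean, config$synonyms)
  tto <- list(sample = tto_ex$sample, exclusions = tto_ex$exclusions,
              summary = NULL, fits = NULL, selection = NULL,
              pattern = NULL, stratified = NULL)
  if (nrow(tto_ex$sample) >= 10) {
    tto$summary <- summarize_tto(tto_ex$sample$days)
    tto$fits <- lapply(TTO_FAMILIES, function(f)
      fit_tto(tto_ex$sample$days, f))
    names(tto$fits) <- TTO_FAMILIES
    tto$selection <- aic_select(tto$fits)
    tto$pattern <- hazard_pattern(tto$selection$best)
    tto$stratified <- stratified_tto(tto_ex$sample, events,
                                     config$tto_clusters)
  }

  res <- structure(list(
    manifest = manifest, config = config, config_hash = hash,
    demographics = demographic_summary(reports[reports$is_target, ,
                                               drop = FALSE]),
    n_cohort = length(target_ids), n_database = nrow(reports),
    reports = reports, events = events,
    signals_pt = signals_pt, signals_soc = signals_soc, venn = venn,
    subgroups = subgroups, sensitivity = sensitivity, tto = tto),
    class = "pv_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

#' @export
print.pv_analysis <- function(x, ...) {
  cat("<pv_analysis>\n")
  if (inherits(x, "pv_analysis_empty")) {
    cat("  cohort emptied at stage:", x$empty_at, "\n")
    print(x$manifest)
    return(invisible(x))
  }
  cat(sprintf("  cohort: %d target reports in a database of %d\n",
              x$n_cohort, x$n_database))
  cat(sprintf("  PT terms tabulated: %d (positive: %d, robust: %d)\n",
              nrow(x$signals_pt), sum(x$signals_pt$positive),
              sum(x$signals_pt$robust)))
  if (!is.null(x$tto$summary)) {
    cat(sprintf("  TTO: n=%d, median %.1f d, best family %s (%s)\n",
                x$tto$summary$n, x$tto$summary$median,
                x$tto$selection$best$family, x$tto$pattern))
  }
  cat("  config hash:", x$config_hash, "\n")
  invisible(x)
}

write_analysis <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(cbind(res$signals_pt, config_hash = res$config_hash),
     "signals_pt.tsv")
  wr(cbind(res$signals_soc, config_hash = res$config_hash),
     "signals_soc.tsv")
  wr(res$sensitivity$persistence, "sensitivity_persistence.tsv")
  wr(res$demographics, "demographics.tsv")
  if (!is.null(res$tto$stratified)) wr(res$tto$stratified, "tto_strata.tsv")
  jsonlite::write_json(
    list(manifest = res$manifest, config_hash = res$config_hash,
         venn = res$venn,
         version = as.character(utils::packageVersion("pvsignal"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Compare a main run against a sensitivity run
#'
#' Outer join on term. A term's signal `persisted` when it is positive in
#' both runs and, in the sensitivity run, retains a ROR lower bound above
#' 1 with at least `min_cases` reports.
#'
#' @param main,sensitivity classified metrics data.frames sharing the term
#'   universe (a warning is issued and blanks filled when they do not).
#' @param min_cases minimum sensitivity-run case count.
#' @return data.frame `term`, `main_positive`, `sens_positive`,
#'   `main_ror`, `sens_ror`, `sens_ror_lower`, `sens_a`, `persisted`.
#' @export
compare_runs <- function(main, sensitivity, min_cases = 3L) {
  as_classified <- function(x) {
    need <- c("term", "positive", "ror", "ror_lower", "a")
    for (col in setdiff(need, names(x))) {
      x[[col]] <- if (col == "term") character(0) else logical(0)
    }
    x
  }
  main <- as_classified(main)
  sensitivity <- as_classified(sensitivity)
  if (!length(intersect(main$term, sensitivity$term))) {
    warning("term sets of the two runs are disjoint; outer join with blanks")
  }
  m <- main[c("term", "positive", "ror", "a")]
  names(m) <- c("term", "main_positive", "main_ror", "main_a")
  s <- sensitivity[c("term", "positive", "ror", "ror_lower", "a")]
  names(s) <- c("term", "sens_positive", "sens_ror", "sens_ror_lower",
                "sens_a")
  out <- merge(m, s, by = "term", all = TRUE)
  out$persisted <- !is.na(out$main_positive) & out$main_positive &
    !is.na(out$sens_positive) & out$sens_positive &
    !is.na(out$sens_ror_lower) & out$sens_ror_lower > 1 &
    !is.na(out$sens_a) & out$sens_a >= min_cases
  out[order(out$term), , drop = FALSE]
}

#' Cross-database concordance of positive signals
#'
#' @param tables_by_source named list (>= 2) of classified metrics
#'   data.frames, one per database.
#' @return data.frame with one row per term in the union: per-source case
#'   counts, within-source report percentages (butterfly-plot-ready) and
#'   positivity, plus a `status` column (`concordant-positive`,
#'   `concordant-negative`, or `source-specific:<names>`).
#' @export
crossdb_concordance <- function(tables_by_source) {
  stopifnot(is.list(tables_by_source), length(tables_by_source) >= 2,
            !is.null(names(tables_by_source)))
  terms <- sort(unique(unlist(lapply(tables_by_source, `[[`, "term"))))
  out <- data.frame(term = terms, stringsAsFactors = FALSE)
  pos <- matrix(FALSE, length(terms), length(tables_by_source),
                dimnames = list(terms, names(tables_by_source)))
  for (src in names(tables_by_source)) {
    tb <- tables_by_source[[src]]
    idx <- match(terms, tb$term)
    n <- ifelse(is.na(idx), 0L, tb$a[idx])
    out[[paste0("n_", src)]] <- n
    out[[paste0("pct_", src)]] <- pct(n, sum(tb$a))
    p <- !is.na(idx) & tb$positive[idx]
    out[[paste0("positive_", src)]] <- p
    pos[, src] <- p
  }
  npos <- rowSums(pos)
  status <- ifelse(npos == ncol(pos), "concordant-positive",
            ifelse(npos == 0, "concordant-negative",
                   paste0("source-specific:",
                          apply(pos, 1, function(r)
                            paste(colnames(pos)[r], collapse = "+")))))
  out$status <- status
  out
}
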