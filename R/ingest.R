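# Cohort construction: case-version deduplication, primary-suspect
# filtering, indication-PT exclusion, age normalization, date audit, and
# assembly of the clean report/event tables used by the contingency stage.

#' Deduplicate case versions
#'
#' FAERS cases are resubmitted as new versions under the same CASEID. For
#' each CASEID the record with the latest FDA_DT is kept; ties on FDA_DT
#' are broken by the higher PRIMARYID. Output is sorted by numeric
#' PRIMARYID, so the operation is deterministic and idempotent.
#'
#' @param data an [srs_data()] object.
#' @return deduplicated [srs_data()]; `meta$duplicates_removed` counts the
#'   removed case versions.
#' @export
deduplicate_reports <- function(data) {
  stopifnot(inherits(data, "srs_data"))
  d <- data$demo
  if (!nrow(d)) return(data)
  ord <- order(d$caseid, -date_sort_key(d$fda_dt),
               -suppressWarnings(as.numeric(d$primaryid)))
  d <- d[ord, , drop = FALSE]
  keep <- d[!duplicated(d$caseid), , drop = FALSE]
  removed <- nrow(d) - nrow(keep)
  keep <- keep[order(suppressWarnings(as.numeric(keep$primaryid))), ,
               drop = FALSE]
  out <- subset_srs(data, keep$primaryid)
  out$demo <- out$demo[match(keep$primaryid, out$demo$primaryid), ,
                       drop = FALSE]
  rownames(out$demo) <- NULL
  out$meta$duplicates_removed <- removed
  out
}

#' Identify reports naming the target drug as primary suspect
#'
#' Matching is exact on the normalized name (case-insensitive, whitespace
#' collapsed) against the synonym list, and requires role code `PS`;
#' secondary-suspect and concomitant entries do not qualify.
#'
#' @param data an [srs_data()] object.
#' @param synonyms character vector of accepted drug names (generic and
#'   brand).
#' @return character vector of qualifying primaryids.
#' @export
target_report_ids <- function(data, synonyms = TARGET_SYNONYMS) {
  stopifnot(inherits(data, "srs_data"), length(synonyms) > 0)
  syn <- normalize_drug_name(synonyms)
  dr <- data$drug
  hit <- dr$role_cod == "PS" & normalize_drug_name(dr$drugname) %in% syn
  unique(dr$primaryid[hit])
}

#' Restrict a database to primary-suspect reports of the target drug
#'
#' @inheritParams target_report_ids
#' @return [srs_data()] containing only the qualifying reports.
#' @export
filter_primary_suspect <- function(data, synonyms = TARGET_SYNONYMS) {
  ids <- target_report_ids(data, synonyms)
  out <- subset_srs(data, ids)
  out$meta$non_target_removed <- nrow(data$demo) - nrow(out$demo)
  out
}

#' Remove indication-related PTs from the event lists
#'
#' PTs that describe the treated condition itself (e.g. deep vein
#' thrombosis for an anticoagulant) would otherwise masquerade as drug
#' reactions. Listed PTs are removed from every report; reports left with
#' no events are dropped entirely and counted.
#'
#' @param data an [srs_data()] object.
#' @param indication_pts character vector of PT names to exclude (may be
#'   empty).
#' @return [srs_data()] with `meta$indication_events_removed` and
#'   `meta$reports_dropped_empty` counters.
#' @export
exclude_indication_pts <- function(data, indication_pts) {
  stopifnot(inherits(data, "srs_data"))
  if (!length(indication_pts)) {
    data$meta$indication_events_removed <- 0L
    data$meta$reports_dropped_empty <- 0L
    return(data)
  }
  hit <- data$reac$pt %in% indication_pts
  removed <- sum(hit)
  reac <- data$reac[!hit, , drop = FALSE]
  still <- unique(reac$primaryid)
  dropped <- setdiff(unique(data$demo$primaryid), still)
  out <- subset_srs(
    srs_data(data$demo, data$drug, reac, data$ther, meta = data$meta),
    still)
  out$meta$indication_events_removed <- removed
  out$meta$reports_dropped_empty <- length(dropped)
  out
}

#' Convert reported ages to years and assign age groups
#'
#' Units: years (`YR`), months (`MON`, divided by 12), days (`DY`, divided
#' by 365.25), decades (`DEC`, multiplied by 10). Groups follow the
#' conventional strata `<18` (`[0, 18)`), `18-64` (`[18, 65)`) and `>=65`
#' (`[65, Inf)`); 65 belongs to the elderly group and 18 to the adult
#' group. Negative ages are flagged invalid and set to missing.
#'
#' @param age_value numeric vector (or character coercible to numeric).
#' @param age_unit character vector of unit codes; unrecognized or missing
#'   units propagate missing.
#' @return data.frame with columns `age_years`, `age_group` and logical
#'   `invalid`.
#' @export
convert_age <- function(age_value, age_unit) {
  v <- suppressWarnings(as.numeric(age_value))
  u <- toupper(trimws(as.character(age_unit)))
  invalid <- !is.na(v) & v < 0
  v[invalid] <- NA_real_
  fac <- rep(NA_real_, length(v))
  fac[u %in% c("YR", "YEAR", "YEARS")] <- 1
  fac[u %in% c("MON", "MONTH", "MONTHS")] <- 1 / 12
  fac[u %in% c("DY", "DAY", "DAYS")] <- 1 / 365.25
  fac[u %in% c("DEC", "DECADE", "DECADES")] <- 10
  years <- v * fac
  group <- cut(years, breaks = c(0, 18, 65, Inf), right = FALSE,
               labels = c("<18", "18-64", ">=65"))
  data.frame(age_years = years, age_group = as.character(group),
             invalid = invalid, stringsAsFactors = FALSE)
}

#' Audit event dates against therapy start dates
#'
#' Reports whose event date strictly precedes the earliest target-drug
#' therapy start date — compared at the shared precision of the two dates —
#' are excluded and logged. Dates of incomparable precision (either
#' missing) pass through untouched; same-day onset is retained.
#'
#' @param data an [srs_data()] object (the target cohort).
#' @param synonyms target-drug synonym list used to find the relevant
#'   therapy rows.
#' @return list with elements `data` (clean [srs_data()]) and `log`
#'   (data.frame `primaryid`, `reason`).
#' @export
audit_dates <- function(data, synonyms = TARGET_SYNONYMS) {
  stopifnot(inherits(data, "srs_data"))
  start <- earliest_target_start(data, synonyms)
  d <- data$demo
  cmp <- compare_partial_dates(start[d$primaryid], d$event_dt)
  bad <- cmp == "before"
  log <- data.frame(primaryid = d$primaryid[bad],
                    reason = rep("event_before_start", sum(bad)),
                    stringsAsFactors = FALSE)
  out <- subset_srs(data, d$primaryid[!bad])
  out$meta$date_audit_removed <- sum(bad)
  list(data = out, log = log)
}

# named vector primaryid -> earliest (by sort key) start date among
# target-drug therapy rows; "" when none
earliest_target_start <- function(data, synonyms = TARGET_SYNONYMS) {
  syn <- normalize_drug_name(synonyms)
  dr <- data$drug[normalize_drug_name(data$drug$drugname) %in% syn, ,
                  drop = FALSE]
  key <- paste(data$ther$primaryid, data$ther$dsg_drug_seq)
  th <- data$ther[key %in% paste(dr$primaryid, dr$drug_seq), , drop = FALSE]
  th <- th[th$start_dt != "", , drop = FALSE]
  out <- stats::setNames(rep("", nrow(data$demo)), data$demo$primaryid)
  if (nrow(th)) {
    th <- th[order(th$primaryid, date_sort_key(th$start_dt)), , drop = FALSE]
    first <- th[!duplicated(th$primaryid), , drop = FALSE]
    out[first$primaryid] <- first$start_dt
  }
  out
}

# map FAERS occupation codes to reporter classes
reporter_class <- function(occp_cod) {
  x <- toupper(trimws(occp_cod))
  out <- rep("missing", length(x))
  out[x %in% c("MD", "PH", "OT", "HP", "RN")] <- "healthcare"
  out[x %in% c("CN", "LW")] <- "consumer"
  out
}

#' Build the clean report and event tables
#'
#' Produces the event-level view consumed by the contingency stage: one row
#' per report with normalized demographics and a target-drug flag, plus one
#' row per unique (report, PT) pair with its SOC. A PT repeated within one
#' report counts once.
#'
#' @param data a deduplicated [srs_data()] object (cohort plus background).
#' @param pt_soc_map data.frame with columns `pt`, `soc`; PTs absent from
#'   the map are assigned SOC `"Unclassified"`.
#' @param synonyms target-drug synonym list.
#' @return list with data.frames `reports` (primaryid, caseid, sex,
#'   age_years, age_group, reporter, country, is_target) and `events`
#'   (primaryid, pt, soc).
#' @export
build_event_table <- function(data, pt_soc_map = pt_vocabulary(),
                              synonyms = TARGET_SYNONYMS) {
  stopifnot(inherits(data, "srs_data"),
            all(c("pt", "soc") %in% names(pt_soc_map)))
  d <- data$demo
  ages <- convert_age(d$age, d$age_cod)
  sex <- toupper(trimws(d$sex))
  sex[!(sex %in% c("M", "F"))] <- "missing"
  reports <- data.frame(
    primaryid = d$primaryid, caseid = d$caseid, sex = sex,
    age_years = ages$age_years,
    age_group = ifelse(is.na(ages$age_group), "missing", ages$age_group),
    reporter = reporter_class(d$occp_cod),
    country = ifelse(d$occr_country == "", "missing", d$occr_country),
    is_target = d$primaryid %in% target_report_ids(data, synonyms),
    stringsAsFactors = FALSE)
  ev <- unique(data$reac[c("primaryid", "pt")])
  soc <- pt_soc_map$soc[match(ev$pt, pt_soc_map$pt)]
  ev$soc <- ifelse(is.na(soc), "Unclassified", soc)
  rownames(ev) <- NULL
  list(reports = reports, events = ev)
}

#' Read a PT-to-SOC mapping table
#'
#' Expects a tab-separated file with columns `pt` and `soc` (one primary
#' SOC per PT). A small synthetic stub is shipped in
#' `system.file("extdata", "pt_soc_map_synthetic.tsv", package = "pvsignal")`;
#' a licensed MedDRA export in the same layout can be supplied instead.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `pt`, `soc`.
#' @export
read_pt_soc_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pt", "soc") %in% names(df)))
  if (anyDuplicated(df$pt)) {
    stop("PT-to-SOC map assigns more than one SOC to a PT", call. = FALSE)
  }
  df[c("pt", "soc")]
}
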