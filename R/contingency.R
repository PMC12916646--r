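# 2x2 contingency tables for drug-event pairs, overall and within strata.
#
# For each event term:
#   a = target-drug reports mentioning the term   b = target reports without
#   c = other reports mentioning the term         d = other reports without
# Counting is report-level: a report contributes at most 1 to a cell for a
# given term, and at SOC level one or more PTs in the SOC count once. The
# background comparator is the rest of the supplied database.

#' Define a stratum for subgroup or sensitivity analysis
#'
#' Filters are conjunctive; an empty specification denotes the full
#' population. Co-medication exclusion removes whole reports containing any
#' listed drug in any role (suspect or concomitant).
#'
#' @param sex,age_group,reporter optional filter values (e.g. `"F"`,
#'   `">=65"`, `"healthcare"`).
#' @param exclude_drugs optional character vector of co-medication names to
#'   exclude report-wise (matched on normalized names over all role codes).
#' @param label optional label; derived from the filters when omitted.
#' @return an object of class `stratum_spec`.
#' @export
stratum_spec <- function(sex = NULL, age_group = NULL, reporter = NULL,
                         exclude_drugs = NULL, label = NULL) {
  spec <- list(sex = sex, age_group = age_group, reporter = reporter,
               exclude_drugs = exclude_drugs)
  if (is.null(label)) {
    parts <- unlist(spec[c("sex", "age_group", "reporter")])
    if (!is.null(exclude_drugs)) {
      parts <- c(parts, paste0("excl:", paste(exclude_drugs, collapse = "+")))
    }
    label <- if (length(parts)) paste(parts, collapse = "/") else "all"
  }
  spec$label <- label
  structure(spec, class = "stratum_spec")
}

#' Apply a stratum specification to the report table
#'
#' @param reports report table from [build_event_table()].
#' @param spec a [stratum_spec()].
#' @param drug optional drug table (`srs_data$drug`), required when the
#'   spec excludes co-medications.
#' @return the filtered report table.
#' @export
apply_stratum <- function(reports, spec, drug = NULL) {
  stopifnot(inherits(spec, "stratum_spec"))
  keep <- rep(TRUE, nrow(reports))
  if (!is.null(spec$sex)) keep <- keep & reports$sex %in% spec$sex
  if (!is.null(spec$age_group)) {
    keep <- keep & reports$age_group %in% spec$age_group
  }
  if (!is.null(spec$reporter)) {
    keep <- keep & reports$reporter %in% spec$reporter
  }
  if (!is.null(spec$exclude_drugs)) {
    if (is.null(drug)) {
      stop("drug table required for co-medication exclusion", call. = FALSE)
    }
    bad_ids <- unique(drug$primaryid[
      normalize_drug_name(drug$drugname) %in%
        normalize_drug_name(spec$exclude_drugs)])
    keep <- keep & !(reports$primaryid %in% bad_ids)
  }
  out <- reports[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build 2x2 contingency tables for every event term in a stratum
#'
#' One table is emitted per term with at least one occurrence among
#' target-drug reports in the stratum; rare terms are retained here and
#' only filtered at classification time (the minimum-case rule belongs to
#' the signal criteria, not to tabulation).
#'
#' @param reports report table (possibly stratified via [apply_stratum()]).
#' @param events event table from [build_event_table()].
#' @param level `"pt"` or `"soc"`.
#' @param stratum label recorded in the output.
#' @return data.frame with columns `term`, `level`, `stratum`, `a`, `b`,
#'   `c`, `d`, `expected` (= (a+b)(a+c)/N). Empty (with a warning) when the
#'   stratum contains no target reports.
#' @export
build_contingency <- function(reports, events, level = c("pt", "soc"),
                              stratum = "all") {
  level <- match.arg(level)
  ids <- reports$primaryid
  tgt <- reports$primaryid[reports$is_target]
  n_target <- length(tgt)
  n_all <- nrow(reports)
  empty <- data.frame(term = character(), level = character(),
                      stratum = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), expected = numeric(),
                      stringsAsFactors = FALSE)
  if (n_target == 0L) {
    warning("no target-drug reports in stratum '", stratum, "'")
    return(empty)
  }
  ev <- events[events$primaryid %in% ids, , drop = FALSE]
  term <- if (level == "pt") ev$pt else ev$soc
  pairs <- unique(data.frame(primaryid = ev$primaryid, term = term,
                             stringsAsFactors = FALSE))
  if (!nrow(pairs)) return(empty)
  in_target <- pairs$primaryid %in% tgt
  a_tab <- table(pairs$term[in_target])
  if (!length(a_tab)) return(empty)
  m_tab <- table(pairs$term)
  terms <- names(a_tab)
  a <- as.integer(a_tab)
  m <- as.integer(m_tab[terms])
  cc <- m - a
  b <- n_target - a
  d <- (n_all - n_target) - cc
  n <- n_all
  out <- data.frame(term = terms, level = level, stratum = stratum,
                    a = a, b = b, c = cc, d = d,
                    expected = as.numeric(a + b) * as.numeric(a + cc) / n,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$a, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
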