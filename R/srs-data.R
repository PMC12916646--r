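# The in-memory container for a spontaneous-report database: four relational
# character tables keyed by PRIMARYID, mirroring the FAERS quarterly files.

DEMO_COLS <- c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
               "sex", "occp_cod", "occr_country")
DRUG_COLS <- c("primaryid", "drug_seq", "role_cod", "drugname")
REAC_COLS <- c("primaryid", "pt")
THER_COLS <- c("primaryid", "dsg_drug_seq", "start_dt")

#' Construct a spontaneous-report database object
#'
#' Bundles the four relational tables of the FAERS dialect (demographics,
#' drugs, reactions, therapy dates) into a single object. All columns are
#' character so that partial dates and leading zeros survive file
#' round-trips; numeric interpretation happens downstream.
#'
#' @param demo data.frame with columns `primaryid, caseid, fda_dt, event_dt,
#'   age, age_cod, sex, occp_cod, occr_country`.
#' @param drug data.frame with columns `primaryid, drug_seq, role_cod,
#'   drugname` (role codes `PS`, `SS`, `C`, `I`).
#' @param reac data.frame with columns `primaryid, pt`.
#' @param ther data.frame with columns `primaryid, dsg_drug_seq, start_dt`.
#' @param meta optional list of bookkeeping counters (e.g. orphan rows
#'   dropped at read time).
#' @return an object of class `srs_data`.
#' @export
srs_data <- function(demo, drug, reac, ther = NULL, meta = list()) {
  if (is.null(ther)) {
    ther <- data.frame(primaryid = character(), dsg_drug_seq = character(),
                       start_dt = character(), stringsAsFactors = FALSE)
  }
  demo <- as_char_df(demo, DEMO_COLS, "demo")
  drug <- as_char_df(drug, DRUG_COLS, "drug")
  reac <- as_char_df(reac, REAC_COLS, "reac")
  ther <- as_char_df(ther, THER_COLS, "ther")
  structure(list(demo = demo, drug = drug, reac = reac, ther = ther,
                 meta = meta),
            class = "srs_data")
}

as_char_df <- function(df, cols, what) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s table is missing columns: %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[cols]
  df[] <- lapply(df, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  rownames(df) <- NULL
  df
}

#' @export
print.srs_data <- function(x, ...) {
  cat("<srs_data>\n")
  cat(sprintf("  reports (DEMO): %d\n", nrow(x$demo)))
  cat(sprintf("  drug rows:      %d\n", nrow(x$drug)))
  cat(sprintf("  reaction rows:  %d\n", nrow(x$reac)))
  cat(sprintf("  therapy rows:   %d\n", nrow(x$ther)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, paste,
        collapse = ",")), sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

# restrict all tables to a set of primaryids, preserving demo order
subset_srs <- function(x, keep_ids) {
  demo <- x$demo[x$demo$primaryid %in% keep_ids, , drop = FALSE]
  srs_data(demo,
           x$drug[x$drug$primaryid %in% keep_ids, , drop = FALSE],
           x$reac[x$reac$primaryid %in% keep_ids, , drop = FALSE],
           x$ther[x$ther$primaryid %in% keep_ids, , drop = FALSE],
           meta = x$meta)
}

#' Normalize a drug name for matching
#'
#' Trims, collapses internal whitespace and upper-cases. Matching against a
#' synonym list is exact after this normalization; no fuzzy matching is
#' attempted (reproducibility over recall).
#'
#' @param x character vector of verbatim drug names.
#' @return normalized character vector.
#' @export
normalize_drug_name <- function(x) {
  toupper(gsub("\\s+", " ", trimws(as.character(x))))
}
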