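# Reading and writing the FAERS ASCII quarterly dialect: '$'-delimited
# tables with a header row, one file per table per quarter
# (DEMOyyQq.txt, DRUGyyQq.txt, REACyyQq.txt, THERyyQq.txt).

#' Write a database as FAERS-dialect quarterly files
#'
#' @param data an [srs_data()] object.
#' @param directory output directory (created if needed).
#' @param quarter quarter label used in the file names, e.g. `"24Q3"`.
#' @return invisibly, a named character vector (the file manifest).
#' @export
write_faers_quarter <- function(data, directory, quarter = "24Q3") {
  stopifnot(inherits(data, "srs_data"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  files <- c(DEMO = file.path(directory, sprintf("DEMO%s.txt", quarter)),
             DRUG = file.path(directory, sprintf("DRUG%s.txt", quarter)),
             REAC = file.path(directory, sprintf("REAC%s.txt", quarter)),
             THER = file.path(directory, sprintf("THER%s.txt", quarter)))
  tabs <- list(DEMO = data$demo, DRUG = data$drug, REAC = data$reac,
               THER = data$ther)
  for (nm in names(files)) {
    utils::write.table(tabs[[nm]], files[[nm]], sep = "$", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
  }
  invisible(files)
}

read_dollar_file <- function(path) {
  df <- utils::read.table(path, sep = "$", header = TRUE, quote = "",
                          comment.char = "", colClasses = "character",
                          stringsAsFactors = FALSE, fill = TRUE,
                          na.strings = character())
  names(df) <- tolower(names(df))
  df
}

#' Read FAERS-dialect quarterly files from a directory
#'
#' All `DEMO*.txt` / `DRUG*.txt` / `REAC*.txt` / `THER*.txt` files found in
#' the directory are read and stacked, so a directory may hold several
#' quarters. DRUG/REAC/THER rows whose PRIMARYID does not appear in DEMO
#' are dropped and counted in `meta$orphans`. Unparseable or partial dates
#' are retained verbatim, never treated as errors.
#'
#' @param directory directory containing the quarterly files. DEMO, DRUG
#'   and REAC are required; THER is optional.
#' @return an [srs_data()] object (pre-deduplication).
#' @export
read_faers_quarter <- function(directory) {
  if (!dir.exists(directory)) {
    stop("directory not found: ", directory, call. = FALSE)
  }
  find <- function(prefix) {
    sort(list.files(directory, pattern = paste0("^", prefix, ".*\\.txt$"),
                    full.names = TRUE, ignore.case = TRUE))
  }
  read_all <- function(prefix, required = TRUE) {
    fs <- find(prefix)
    if (!length(fs)) {
      if (required) stop("no ", prefix, " file found in ", directory,
                         call. = FALSE)
      return(NULL)
    }
    do.call(rbind, lapply(fs, read_dollar_file))
  }
  demo <- read_all("DEMO")
  drug <- read_all("DRUG")
  reac <- read_all("REAC")
  ther <- read_all("THER", required = FALSE)
  if (is.null(ther)) {
    ther <- data.frame(primaryid = character(), dsg_drug_seq = character(),
                       start_dt = character(), stringsAsFactors = FALSE)
  }
  ids <- demo$primaryid
  orphans <- c(drug = sum(!(drug$primaryid %in% ids)),
               reac = sum(!(reac$primaryid %in% ids)),
               ther = sum(!(ther$primaryid %in% ids)))
  srs_data(demo,
           drug[drug$primaryid %in% ids, , drop = FALSE],
           reac[reac$primaryid %in% ids, , drop = FALSE],
           ther[ther$primaryid %in% ids, , drop = FALSE],
           meta = list(orphans = orphans))
}
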