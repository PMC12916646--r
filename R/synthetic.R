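# Synthetic spontaneous-report generator.
#
# Emulates the statistical structure of a spontaneous reporting system at
# desk scale: Zipf-distributed background PT frequencies, multi-drug reports
# with role codes, injected drug-PT associations of known relative risk,
# case-version duplicates, demographic missingness, partial dates, and
# per-cluster time-to-onset distributions. The returned truth object records
# everything needed to validate downstream stages.

TARGET_SYNONYMS <- c("FONDAPARINUX SODIUM", "ARIXTRA", "QUIXIDAR")

#' Synthetic PT vocabulary with a stub SOC map
#'
#' The first ranks are real bleeding/haematology/rash terms (so cluster
#' analyses are meaningful); the remainder are generic `PT_####` codes
#' assigned round-robin to generic SOC names. This is a synthetic stand-in
#' for a licensed MedDRA dictionary, usable wherever a PT-to-SOC map is
#' required.
#'
#' @param size vocabulary size (>= 20).
#' @return data.frame with columns `pt`, `soc`, `cluster`
#'   (`bleeding` / `rash` / `other`).
#' @export
pt_vocabulary <- function(size = 200) {
  stopifnot(size >= 20)
  named <- data.frame(
    pt = c("Haematoma", "Anaemia", "Haemorrhage", "Muscle haemorrhage",
           "Cerebral haemorrhage", "Melaena", "Haematemesis",
           "Gastrointestinal haemorrhage", "Epistaxis", "Haematuria",
           "Thrombocytopenia", "Heparin-induced thrombocytopenia",
           "Haemoglobin decreased", "Rash", "Urticaria", "Pruritus",
           "Skin necrosis", "Renal failure", "Coma", "Dyspnoea"),
    soc = c("Vascular disorders", "Blood and lymphatic system disorders",
            "Vascular disorders", "Vascular disorders",
            "Nervous system disorders", "Gastrointestinal disorders",
            "Gastrointestinal disorders", "Gastrointestinal disorders",
            "Respiratory, thoracic and mediastinal disorders",
            "Renal and urinary disorders",
            "Blood and lymphatic system disorders",
            "Blood and lymphatic system disorders", "Investigations",
            "Skin and subcutaneous tissue disorders",
            "Skin and subcutaneous tissue disorders",
            "Skin and subcutaneous tissue disorders",
            "Skin and subcutaneous tissue disorders",
            "Renal and urinary disorders", "Nervous system disorders",
            "Respiratory, thoracic and mediastinal disorders"),
    cluster = c("bleeding", "other", "bleeding", "bleeding", "bleeding",
                "bleeding", "bleeding", "bleeding", "bleeding", "bleeding",
                "other", "other", "other", "rash", "rash", "rash", "rash",
                "other", "other", "other"),
    stringsAsFactors = FALSE)
  n_extra <- size - nrow(named)
  if (n_extra > 0) {
    socs <- c("General disorders and administration site conditions",
              "Nervous system disorders", "Gastrointestinal disorders",
              "Investigations", "Cardiac disorders",
              "Infections and infestations", "Psychiatric disorders",
              "Musculoskeletal and connective tissue disorders",
              "Metabolism and nutrition disorders", "Eye disorders")
    extra <- data.frame(
      pt = sprintf("PT_%04d", seq_len(n_extra)),
      soc = socs[(seq_len(n_extra) - 1L) %% length(socs) + 1L],
      cluster = "other", stringsAsFactors = FALSE)
    named <- rbind(named, extra)
  }
  named
}

check_simplex <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("%s must be a probability vector summing to 1 (got sum %.12f)",
                 what, sum(p)), call. = FALSE)
  }
  invisible(p)
}

#' Configuration for the synthetic spontaneous-report generator
#'
#' Defaults reproduce the study conditions of the reference analysis:
#' demographic mixtures matching the observed FAERS report composition,
#' a mean of 3 events per report, 61% of reports with unusable therapy/event
#' dates, and a default time-to-onset cluster following a log-logistic law
#' with scale 7.8 days and shape 1.2 (bleeding and rash clusters with
#' medians 7 and 5.5 days).
#'
#' @param n_reports number of base reports (before duplicate injection).
#' @param target_share probability in (0,1) that a report is exposed to the
#'   target drug (as primary suspect).
#' @param n_background_drugs number of generic background drug names, in
#'   addition to the named co-medications (aspirin, prednisone,
#'   hydroxychloroquine).
#' @param pt_vocab_size size of the PT vocabulary.
#' @param zipf_exponent exponent (> 0) of the Zipf law for background PT
#'   frequencies.
#' @param injected_signals data.frame with columns `pt`, `rr`: relative
#'   reporting-rate multipliers (>= 0) applied to exposed reports. PTs must
#'   belong to the vocabulary.
#' @param events_per_report mean number of events per report.
#' @param sex_probs,age_group_probs,reporter_probs probability vectors
#'   (must each sum to 1) over (male, female, missing),
#'   (<18, 18-64, >=65, missing) and (healthcare, consumer, missing).
#' @param duplicate_rate fraction in `[0,1)` of base reports that receive an
#'   extra case version (same CASEID, higher PRIMARYID, FDA_DT + 1..90 days).
#' @param missing_date_rate fraction of reports whose therapy start and/or
#'   event date is blanked.
#' @param partial_date_rate fraction of remaining dates degraded to month or
#'   year precision.
#' @param tto_spec named list of per-cluster time-to-onset distributions,
#'   each `list(family, scale, shape)` with family one of `weibull`,
#'   `loglogistic`, `lognormal`. Must contain a `default` entry.
#' @param seed integer seed; the generator is byte-deterministic given the
#'   full configuration.
#' @return an object of class `srs_config`.
#' @export
srs_config <- function(n_reports = 20000L,
                       target_share = 0.05,
                       n_background_drugs = 40L,
                       pt_vocab_size = 200L,
                       zipf_exponent = 1.1,
                       injected_signals = NULL,
                       events_per_report = 3,
                       sex_probs = c(male = 0.3465, female = 0.4851,
                                     missing = 0.1684),
                       age_group_probs = c(under18 = 0.0049, adult = 0.2716,
                                           elderly = 0.3826, missing = 0.3409),
                       reporter_probs = c(healthcare = 0.5023,
                                          consumer = 0.4696,
                                          missing = 0.0281),
                       duplicate_rate = 0.05,
                       missing_date_rate = 0.61,
                       partial_date_rate = 0.05,
                       tto_spec = list(
                         default  = list(family = "loglogistic",
                                         scale = 7.8, shape = 1.2),
                         bleeding = list(family = "loglogistic",
                                         scale = 7.0, shape = 1.3),
                         rash     = list(family = "loglogistic",
                                         scale = 5.5, shape = 1.4)),
                       seed = 1L) {
  stopifnot(n_reports >= 0, length(n_reports) == 1)
  if (target_share <= 0 || target_share >= 1) {
    stop("target_share must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(zipf_exponent > 0, events_per_report > 0,
            duplicate_rate >= 0, duplicate_rate < 1,
            missing_date_rate >= 0, missing_date_rate <= 1,
            partial_date_rate >= 0, partial_date_rate < 1)
  check_simplex(sex_probs, "sex_probs")
  check_simplex(age_group_probs, "age_group_probs")
  check_simplex(reporter_probs, "reporter_probs")
  vocab <- pt_vocabulary(pt_vocab_size)
  if (is.null(injected_signals)) {
    injected_signals <- data.frame(pt = character(), rr = numeric(),
                                   stringsAsFactors = FALSE)
  }
  injected_signals <- as.data.frame(injected_signals,
                                    stringsAsFactors = FALSE)
  stopifnot(all(c("pt", "rr") %in% names(injected_signals)))
  if (any(injected_signals$rr < 0)) {
    stop("relative-risk multipliers must be >= 0", call. = FALSE)
  }
  bad <- setdiff(injected_signals$pt, vocab$pt)
  if (length(bad)) {
    stop("injected signal PTs outside the vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(tto_spec$default)) {
    stop("tto_spec must contain a 'default' cluster", call. = FALSE)
  }
  for (s in tto_spec) {
    stopifnot(s$family %in% c("weibull", "loglogistic", "lognormal"),
              s$scale > 0, s$shape > 0)
  }
  structure(list(
    n_reports = as.integer(n_reports), target_share = target_share,
    n_background_drugs = as.integer(n_background_drugs),
    pt_vocab_size = as.integer(pt_vocab_size),
    zipf_exponent = zipf_exponent,
    injected_signals = injected_signals,
    events_per_report = events_per_report,
    sex_probs = sex_probs, age_group_probs = age_group_probs,
    reporter_probs = reporter_probs,
    duplicate_rate = duplicate_rate,
    missing_date_rate = missing_date_rate,
    partial_date_rate = partial_date_rate,
    tto_spec = tto_spec, seed = as.integer(seed)),
    class = "srs_config")
}

degrade_dates <- function(dates, rate) {
  # degrade a fraction of non-missing day-precision dates to month or year
  n <- length(dates)
  hit <- stats::runif(n) < rate & dates != ""
  if (any(hit)) {
    to_year <- hit & stats::runif(n) < 1 / 3
    to_month <- hit & !to_year
    dates[to_month] <- substr(dates[to_month], 1L, 6L)
    dates[to_year] <- substr(dates[to_year], 1L, 4L)
  }
  dates
}

#' Generate a synthetic spontaneous-report database
#'
#' Draws a database of reports under the configured conditions and returns
#' both the relational data and a ground-truth object. For each report the
#' vocabulary PT `k` is included independently with probability
#' `background_rate(k)` (Zipf-scaled so the expected events per report match
#' the configured mean), multiplied by `rr(k)` for reports exposed to the
#' target drug (capped at 1). One therapy start date and one event date are
#' attached per report, with the event date offset by a time-to-onset draw
#' from the report's PT cluster.
#'
#' @param config an [srs_config()] object.
#' @return list with elements `data` (an [srs_data()] object) and `truth`
#'   (class `srs_truth`: injected signals with realized exposed/unexposed
#'   counts, exposure totals, TTO parameters, duplicate primaryids, seed).
#' @export
generate_srs <- function(config) {
  stopifnot(inherits(config, "srs_config"))
  set.seed(config$seed)
  n <- config$n_reports
  vocab <- pt_vocabulary(config$pt_vocab_size)
  V <- nrow(vocab)

  if (n == 0L) {
    empty <- srs_data(
      demo = as.data.frame(stats::setNames(rep(list(character()), length(DEMO_COLS)), DEMO_COLS)),
      drug = as.data.frame(stats::setNames(rep(list(character()), length(DRUG_COLS)), DRUG_COLS)),
      reac = as.data.frame(stats::setNames(rep(list(character()), length(REAC_COLS)), REAC_COLS)))
    truth <- structure(list(seed = config$seed, n_reports = 0L,
                            n_exposed = 0L,
                            injected_signals = config$injected_signals,
                            pt_counts = data.frame(),
                            tto_spec = config$tto_spec,
                            duplicate_primaryids = character()),
                       class = "srs_truth")
    return(list(data = empty, truth = truth))
  }

  # --- exposure and events ---------------------------------------------
  w <- seq_len(V)^(-config$zipf_exponent)
  base_p <- pmin(w / sum(w) * config$events_per_report, 1)
  rr <- rep(1, V)
  if (nrow(config$injected_signals)) {
    idx <- match(config$injected_signals$pt, vocab$pt)
    rr[idx] <- config$injected_signals$rr
  }
  exposed <- stats::runif(n) < config$target_share

  ev_report <- integer(0)
  ev_pt <- integer(0)
  for (k in seq_len(V)) {
    p <- ifelse(exposed, pmin(base_p[k] * rr[k], 1), base_p[k])
    hit <- which(stats::runif(n) < p)
    ev_report <- c(ev_report, hit)
    ev_pt <- c(ev_pt, rep.int(k, length(hit)))
  }
  ord <- order(ev_report, ev_pt)
  ev_report <- ev_report[ord]
  ev_pt <- ev_pt[ord]

  # --- demographics -----------------------------------------------------
  sex <- sample(c("M", "F", ""), n, replace = TRUE, prob = config$sex_probs)
  grp <- sample(c("under18", "adult", "elderly", "missing"), n,
                replace = TRUE, prob = config$age_group_probs)
  age_years <- rep(NA_real_, n)
  age_years[grp == "under18"] <- round(stats::runif(sum(grp == "under18"), 1, 17))
  age_years[grp == "adult"] <- round(stats::runif(sum(grp == "adult"), 18, 64))
  age_years[grp == "elderly"] <- round(stats::runif(sum(grp == "elderly"), 65, 95))
  age <- ifelse(is.na(age_years), "", format(age_years, trim = TRUE))
  age_cod <- ifelse(is.na(age_years), "", "YR")
  dec <- !is.na(age_years) & stats::runif(n) < 0.02
  age[dec] <- format(age_years[dec] / 10, trim = TRUE)
  age_cod[dec] <- "DEC"
  occp <- sample(c("MD", "CN", ""), n, replace = TRUE,
                 prob = config$reporter_probs)
  country <- sample(c("US", "FR", "JP", "IE", "DE", ""), n, replace = TRUE,
                    prob = c(0.35, 0.28, 0.07, 0.06, 0.05, 0.19))

  # --- dates and time-to-onset -----------------------------------------
  origin <- as.Date("2004-01-01")
  span <- as.integer(as.Date("2024-09-30") - origin)
  fda <- origin + sample.int(span, n, replace = TRUE)
  fda_dt <- format(fda, "%Y%m%d")
  start <- fda - sample(10:120, n, replace = TRUE)
  start_dt <- format(start, "%Y%m%d")

  # report cluster = cluster of its first (most frequent) event, else default
  first_ev <- ev_pt[!duplicated(ev_report)]
  cluster <- rep("default", n)
  cluster[unique(ev_report)] <- vocab$cluster[first_ev]
  cluster[!(cluster %in% names(config$tto_spec))] <- "default"
  tto <- numeric(n)
  for (cl in unique(cluster)) {
    sel <- cluster == cl
    tto[sel] <- draw_tto(sum(sel), config$tto_spec[[cl]])
  }
  event_dt <- date_add_days(start_dt, floor(tto))

  miss <- stats::runif(n) < config$missing_date_rate
  which_miss <- sample(c("start", "event", "both"), n, replace = TRUE)
  start_dt[miss & which_miss %in% c("start", "both")] <- ""
  event_dt[miss & which_miss %in% c("event", "both")] <- ""
  start_dt <- degrade_dates(start_dt, config$partial_date_rate)
  event_dt <- degrade_dates(event_dt, config$partial_date_rate)

  # --- drugs ------------------------------------------------------------
  background_drugs <- c("ASPIRIN", "PREDNISONE", "HYDROXYCHLOROQUINE",
                        sprintf("DRUG_%03d", seq_len(config$n_background_drugs)))
  primaryid <- as.character(1000000L + seq_len(n))
  caseid <- as.character(500000L + seq_len(n))

  # one primary-suspect drug per report plus 0-2 co-medications
  n_co <- sample(0:2, n, replace = TRUE)
  k <- n_co + 1L
  rid <- rep(seq_len(n), k)
  seqs <- as.character(sequence(k))
  is_first <- !duplicated(rid)
  drugname <- sample(background_drugs, length(rid), replace = TRUE)
  drugname[is_first & exposed[rid]] <-
    sample(TARGET_SYNONYMS, sum(exposed), replace = TRUE)
  role <- sample(c("SS", "C"), length(rid), replace = TRUE)
  role[is_first] <- "PS"
  drug <- data.frame(primaryid = primaryid[rid], drug_seq = seqs,
                     role_cod = role, drugname = drugname,
                     stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = primaryid[rid], dsg_drug_seq = seqs,
                     start_dt = start_dt[rid], stringsAsFactors = FALSE)

  demo <- data.frame(primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
                     event_dt = event_dt, age = age, age_cod = age_cod,
                     sex = sex, occp_cod = occp, occr_country = country,
                     stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = primaryid[ev_report],
                     pt = vocab$pt[ev_pt], stringsAsFactors = FALSE)

  # --- duplicate case versions -----------------------------------------
  n_dup <- floor(config$duplicate_rate * n)
  dup_ids <- character(0)
  if (n_dup > 0) {
    base_idx <- sort(sample.int(n, n_dup))
    dup_ids <- as.character(1000000L + n + seq_len(n_dup))
    dup_demo <- demo[base_idx, , drop = FALSE]
    dup_demo$primaryid <- dup_ids
    dup_demo$fda_dt <- date_add_days(dup_demo$fda_dt,
                                     sample(1:90, n_dup, replace = TRUE))
    demo <- rbind(demo, dup_demo)
    remap <- function(df) {
      sub <- df[df$primaryid %in% primaryid[base_idx], , drop = FALSE]
      sub$primaryid <- dup_ids[match(sub$primaryid, primaryid[base_idx])]
      rbind(df, sub)
    }
    drug <- remap(drug)
    reac <- remap(reac)
    ther <- remap(ther)
  }

  # --- truth ------------------------------------------------------------
  pt_counts <- data.frame(
    pt = vocab$pt,
    rr = rr,
    n_exposed_with = tabulate2(ev_pt[exposed[ev_report]], V),
    n_unexposed_with = tabulate2(ev_pt[!exposed[ev_report]], V),
    stringsAsFactors = FALSE)
  truth <- structure(list(
    seed = config$seed, n_reports = n, n_exposed = sum(exposed),
    injected_signals = config$injected_signals,
    pt_counts = pt_counts, tto_spec = config$tto_spec,
    duplicate_primaryids = dup_ids), class = "srs_truth")

  list(data = srs_data(demo, drug, reac, ther), truth = truth)
}

tabulate2 <- function(x, nbins) tabulate(x, nbins = nbins)

#' Write / read the generator ground truth
#'
#' The truth object round-trips losslessly through a JSON sidecar file.
#'
#' @param truth an `srs_truth` object.
#' @param path file path for the JSON sidecar.
#' @return `write_truth` returns `path` invisibly; `read_truth` returns the
#'   `srs_truth` object.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "srs_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$injected_signals <- as.data.frame(x$injected_signals,
                                      stringsAsFactors = FALSE)
  if (!nrow(x$injected_signals)) {
    x$injected_signals <- data.frame(pt = character(), rr = numeric(),
                                     stringsAsFactors = FALSE)
  }
  if (!nrow(x$injected_signals)) {
    x$injected_signals$rr <- as.numeric(x$injected_signals$rr)
  } else {
    x$injected_signals$rr <- as.numeric(x$injected_signals$rr)
    x$injected_signals$pt <- as.character(x$injected_signals$pt)
  }
  x$pt_counts <- as.data.frame(x$pt_counts, stringsAsFactors = FALSE)
  if (nrow(x$pt_counts)) {
    x$pt_counts$rr <- as.numeric(x$pt_counts$rr)
    x$pt_counts$n_exposed_with <- as.integer(x$pt_counts$n_exposed_with)
    x$pt_counts$n_unexposed_with <- as.integer(x$pt_counts$n_unexposed_with)
  }
  x$duplicate_primaryids <- as.character(x$duplicate_primaryids)
  x$seed <- as.integer(x$seed)
  x$n_reports <- as.integer(x$n_reports)
  x$n_exposed <- as.integer(x$n_exposed)
  structure(x, class = "srs_truth")
}
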