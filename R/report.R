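# Reporting layer: percentage arithmetic, demographic composition tables
# and publication-style signal table formatting.

#' Percentage of a count within a total
#'
#' `pct(2765, 5700)` is `48.51`: the plain rounded percentage used
#' throughout the demographic and TTO summaries.
#'
#' @param n count (vector).
#' @param total denominator.
#' @param digits decimals to round to.
#' @return numeric percentage(s) on the 0-100 scale.
#' @export
pct <- function(n, total, digits = 2) {
  round(100 * n / total, digits)
}

#' Demographic composition of a report table
#'
#' Counts and percentages by sex, age group and reporter class, with
#' missing values kept as their own stratum.
#'
#' @param reports report table from [build_event_table()].
#' @return data.frame with columns `characteristic`, `stratum`, `n`, `pct`.
#' @export
demographic_summary <- function(reports) {
  one <- function(chr, values, col) {
    n <- vapply(values, function(v) sum(reports[[col]] == v), integer(1))
    data.frame(characteristic = chr, stratum = values, n = n,
               pct = pct(n, nrow(reports)), stringsAsFactors = FALSE)
  }
  rbind(one("sex", c("M", "F", "missing"), "sex"),
        one("age_group", c("<18", "18-64", ">=65", "missing"), "age_group"),
        one("reporter", c("healthcare", "consumer", "missing"), "reporter"))
}

#' Format a classified signal table for publication-style output
#'
#' Renders estimates to two decimals with their intervals in parentheses
#' and an asterisk on each algorithm meeting its positivity criterion,
#' mirroring the usual layout of PT-level signal tables.
#'
#' @param metrics classified metrics from [compute_signal_metrics()].
#' @return data.frame of character columns `term`, `n`, `ror`, `prr`,
#'   `chi2`, `ebgm`, `ic`, `consensus`.
#' @export
format_signal_table <- function(metrics) {
  star <- function(flag) ifelse(flag, "*", "")
  fmt <- function(x) formatC(x, format = "f", digits = 2)
  data.frame(
    term = metrics$term,
    n = metrics$a,
    ror = sprintf("%s%s (%s, %s)", fmt(metrics$ror), star(metrics$ror_pos),
                  fmt(metrics$ror_lower), fmt(metrics$ror_upper)),
    prr = sprintf("%s%s (%s, %s)", fmt(metrics$prr), star(metrics$prr_pos),
                  fmt(metrics$prr_lower), fmt(metrics$prr_upper)),
    chi2 = fmt(metrics$chi2),
    ebgm = sprintf("%s%s (%s)", fmt(metrics$ebgm), star(metrics$mgps_pos),
                   fmt(metrics$ebgm05)),
    ic = sprintf("%s%s (%s)", fmt(metrics$ic), star(metrics$bcpnn_pos),
                 fmt(metrics$ic025)),
    consensus = metrics$consensus,
    stringsAsFactors = FALSE)
}
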