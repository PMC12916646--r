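# Disproportionality statistics: ROR, PRR with Pearson chi-square, and the
# BCPNN information component. The gamma-Poisson shrinker lives in gps.R.

#' Reporting odds ratio with 95% confidence interval
#'
#' ROR = ad/bc with the log-normal interval
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero the Haldane-Anscombe correction (+0.5 to all four cells) is applied
#' and flagged; the published formula stays exact on nonzero tables.
#'
#' @param a,b,c,d contingency-table cells (vectors recycle).
#' @param z normal quantile for the interval (1.96 for 95%).
#' @return data.frame with columns `ror`, `ror_lower`, `ror_upper`,
#'   `ror_corrected`.
#' @export
ror_ci <- function(a, b, c, d, z = 1.96) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  a2 <- a + 0.5 * corrected
  b2 <- b + 0.5 * corrected
  c2 <- c + 0.5 * corrected
  d2 <- d + 0.5 * corrected
  ror <- (a2 * d2) / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  data.frame(ror = ror,
             ror_lower = exp(log(ror) - z * se),
             ror_upper = exp(log(ror) + z * se),
             ror_corrected = corrected)
}

#' Proportional reporting ratio with chi-square statistic
#'
#' PRR = `[a/(a+b)] / [c/(c+d)]`; the chi-square is the Pearson statistic
#' of the 2x2 table (no continuity correction by default; set
#' `yates = TRUE` for the corrected statistic). The PRR interval uses the
#' log-normal standard error `sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`; it is
#' reported but feeds no signal criterion. A zero denominator (`c = 0` or
#' `a + b = 0`) yields an undefined PRR, flagged as `NA`.
#'
#' @inheritParams ror_ci
#' @param yates apply the Yates continuity correction to the chi-square.
#' @return data.frame with columns `prr`, `prr_lower`, `prr_upper`, `chi2`.
#' @export
prr_chi2 <- function(a, b, c, d, z = 1.96, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  prr <- ifelse(a + b > 0 & c > 0,
                (a / (a + b)) / (c / (c + d)), NA_real_)
  se <- ifelse(!is.na(prr) & a > 0,
               sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)), NA_real_)
  lower <- exp(log(prr) - z * se)
  upper <- exp(log(prr) + z * se)
  det <- a * d - b * c
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0,
                 if (yates) n * pmax(abs(det) - n / 2, 0)^2 / denom
                 else n * det^2 / denom,
                 NA_real_)
  data.frame(prr = prr, prr_lower = lower, prr_upper = upper, chi2 = chi2)
}

#' BCPNN information component with lower credibility bound
#'
#' The information component IC = log2 of the observed-to-expected
#' reporting ratio under the Bayesian confidence propagation model with
#' Beta marginal priors (`alpha1 = beta1 = 1`, `alpha = beta = 2`) and the
#' joint prior count chosen so the prior IC expectation vanishes. The
#' point estimate is the exact posterior mean of IC under the conjugate
#' Beta posteriors (digamma form) and the posterior variance is exact
#' (trigamma form); the 95% bound is the normal approximation
#' `IC - z * sd`. Set `z = 2` for legacy two-standard-deviation intervals.
#'
#' @inheritParams ror_ci
#' @return data.frame with columns `ic`, `ic025`, `ic975`.
#' @export
bcpnn_ic <- function(a, b, c, d, z = 1.96) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n1 <- a + b   # target-drug reports
  m1 <- a + c   # reports with the event
  alpha1 <- 1; alpha <- 2
  beta1 <- 1; beta <- 2
  g11 <- 1
  gamma <- g11 * (n + alpha) * (n + beta) / ((n + alpha1) * (n + beta1))
  e_ic <- (digamma(a + g11) - digamma(n + gamma) -
           (digamma(n1 + alpha1) - digamma(n + alpha)) -
           (digamma(m1 + beta1) - digamma(n + beta))) / log(2)
  v_ic <- (trigamma(a + g11) - trigamma(n + gamma) +
           trigamma(n1 + alpha1) - trigamma(n + alpha) +
           trigamma(m1 + beta1) - trigamma(n + beta)) / log(2)^2
  sd_ic <- sqrt(v_ic)
  data.frame(ic = e_ic, ic025 = e_ic - z * sd_ic, ic975 = e_ic + z * sd_ic)
}

#' Apply the four positivity criteria and count the consensus
#'
#' Criteria: ROR+ iff the ROR 95% lower bound exceeds 1 with at least
#' `min_cases` reports; PRR+ iff PRR >= 2, chi-square >= 4 and at least
#' `min_cases` reports; BCPNN+ iff IC025 > 0; MGPS+ iff EBGM05 > 2.
#' A term is `positive` when at least one flag holds and `robust` when all
#' four hold. Undefined metrics yield a FALSE flag.
#'
#' @param metrics data.frame holding columns `a`, `ror_lower`, `prr`,
#'   `chi2`, `ic025`, `ebgm05` (as produced by [compute_signal_metrics()]).
#' @param min_cases minimum report count for the frequentist criteria.
#' @return `metrics` with logical columns `ror_pos`, `prr_pos`,
#'   `bcpnn_pos`, `mgps_pos`, integer `consensus` and logicals `positive`,
#'   `robust` appended.
#' @export
classify_signals <- function(metrics, min_cases = 3L) {
  flag <- function(x) !is.na(x) & x
  metrics$ror_pos <- flag(metrics$ror_lower > 1) & metrics$a >= min_cases
  metrics$prr_pos <- flag(metrics$prr >= 2) & flag(metrics$chi2 >= 4) &
    metrics$a >= min_cases
  metrics$bcpnn_pos <- flag(metrics$ic025 > 0)
  metrics$mgps_pos <- flag(metrics$ebgm05 > 2)
  metrics$consensus <- metrics$ror_pos + metrics$prr_pos +
    metrics$bcpnn_pos + metrics$mgps_pos
  metrics$positive <- metrics$consensus >= 1L
  metrics$robust <- metrics$consensus == 4L
  metrics
}

#' Compute all four disproportionality statistics for a set of tables
#'
#' Convenience wrapper: ROR, PRR/chi-square and IC are computed per table;
#' the gamma-Poisson shrinker prior is fitted across all supplied tables
#' (they constitute the database for shrinkage purposes) unless an
#' existing prior is passed, then EBGM/EBGM05 are evaluated and the
#' positivity flags appended.
#'
#' @param tables data.frame from [build_contingency()].
#' @param prior optional [gps_prior()]; fitted from `tables` when `NULL`.
#' @param yates,ic_z,min_cases algorithm options (see [prr_chi2()],
#'   [bcpnn_ic()], [classify_signals()]).
#' @return the metrics data.frame with an attribute `"gps_prior"`.
#' @export
compute_signal_metrics <- function(tables, prior = NULL, yates = FALSE,
                                   ic_z = 1.96, min_cases = 3L) {
  if (!nrow(tables)) return(tables)
  out <- cbind(tables,
               ror_ci(tables$a, tables$b, tables$c, tables$d),
               prr_chi2(tables$a, tables$b, tables$c, tables$d,
                        yates = yates),
               bcpnn_ic(tables$a, tables$b, tables$c, tables$d, z = ic_z))
  if (is.null(prior)) {
    prior <- gps_fit(tables$a, tables$expected)
  }
  eb <- gps_ebgm(tables$a, tables$expected, prior)
  out$ebgm <- eb$ebgm
  out$ebgm05 <- eb$ebgm05
  out <- classify_signals(out, min_cases = min_cases)
  attr(out, "gps_prior") <- prior
  out
}

#' Consensus partition of positive signals across the four algorithms
#'
#' @param metrics classified metrics from [compute_signal_metrics()] or
#'   [classify_signals()].
#' @return list with `per_algorithm` (named totals), `by_exactly`
#'   (terms positive by exactly 1..4 algorithms) and `any_positive`.
#' @export
consensus_venn <- function(metrics) {
  per <- c(ROR = sum(metrics$ror_pos), PRR = sum(metrics$prr_pos),
           BCPNN = sum(metrics$bcpnn_pos), MGPS = sum(metrics$mgps_pos))
  by_exact <- vapply(1:4, function(k) sum(metrics$consensus == k),
                     integer(1))
  names(by_exact) <- paste0("exactly_", 1:4)
  list(per_algorithm = per, by_exactly = by_exact,
       any_positive = sum(metrics$consensus >= 1L))
}
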