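# The four disproportionality algorithms against independent oracles:
# hand arithmetic for ROR/PRR, base chisq.test for the Pearson statistic,
# Monte-Carlo posterior sampling for the BCPNN, and closed-form /
# quadrature gamma posteriors for the shrinker.

test_that("ROR and its interval match hand-computed values on the reference table", {
  # a=10, b=90, c=100, d=9900: ROR = ad/bc = 11;
  # CI = exp(ln 11 +/- 1.96 * sqrt(1/10 + 1/90 + 1/100 + 1/9900))
  out <- ror_ci(10, 90, 100, 9900)
  expect_equal(out$ror, 11)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(out$ror_lower, exp(log(11) - 1.96 * se), tolerance = 1e-12)
  expect_equal(out$ror_upper, exp(log(11) + 1.96 * se), tolerance = 1e-12)
  expect_equal(round(c(out$ror_lower, out$ror_upper), 2), c(5.56, 21.76))
  expect_false(out$ror_corrected)
  # symmetric table
  sym <- ror_ci(5, 5, 5, 5)
  expect_equal(sym$ror, 1)
  expect_lt(sym$ror_lower, 1)
  expect_gt(sym$ror_upper, 1)
})

test_that("a zero cell triggers the continuity correction with a flag", {
  out <- ror_ci(3, 0, 10, 1000)
  expect_true(out$ror_corrected)
  expect_equal(out$ror, (3.5 * 1000.5) / (0.5 * 10.5), tolerance = 1e-12)
  expect_true(is.finite(out$ror_lower) && is.finite(out$ror_upper))
})

test_that("PRR and chi-square match hand arithmetic and the base oracle", {
  out <- prr_chi2(10, 90, 100, 9900)
  expect_equal(out$prr, 10)  # (10/100) / (100/10000)
  # independent oracle: Pearson statistic without continuity correction
  oracle <- suppressWarnings(
    stats::chisq.test(matrix(c(10, 90, 100, 9900), 2, byrow = TRUE),
                      correct = FALSE))
  expect_equal(out$chi2, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(round(out$chi2, 1), 74.4)
  yat <- prr_chi2(10, 90, 100, 9900, yates = TRUE)
  oracle_y <- suppressWarnings(
    stats::chisq.test(matrix(c(10, 90, 100, 9900), 2, byrow = TRUE),
                      correct = TRUE))
  expect_equal(yat$chi2, unname(oracle_y$statistic), tolerance = 1e-10)
  # independence: PRR = 1, chi2 = 0
  ind <- prr_chi2(10, 90, 100, 900)
  expect_equal(ind$prr, 1)
  expect_equal(ind$chi2, 0)
  # zero denominator -> undefined with NA
  expect_true(is.na(prr_chi2(5, 5, 0, 100)$prr))
})

test_that("BCPNN posterior moments match a Monte-Carlo oracle within 0.02 bits", {
  set.seed(424242)
  mc_ic <- function(a, b, c, d, draws = 1e6) {
    n <- a + b + c + d; n1 <- a + b; m1 <- a + c
    gamma <- (n + 2)^2 / ((n + 1)^2)
    p11 <- stats::rbeta(draws, 1 + a, gamma - 1 + n - a)
    p1 <- stats::rbeta(draws, 1 + n1, 1 + n - n1)
    p2 <- stats::rbeta(draws, 1 + m1, 1 + n - m1)
    log2(p11 / (p1 * p2))
  }
  cases <- list(c(10, 90, 100, 9900), c(3, 47, 20, 930), c(50, 150, 400, 9400))
  for (cell in cases) {
    draws <- mc_ic(cell[1], cell[2], cell[3], cell[4])
    out <- bcpnn_ic(cell[1], cell[2], cell[3], cell[4])
    expect_lt(abs(out$ic - mean(draws)), 0.02)
    expect_lt(abs((out$ic - out$ic025) / 1.96 - stats::sd(draws)), 0.02)
  }
})

test_that("BCPNN limits: independence near zero, empty cell below zero", {
  # exact independence with large cells
  ind <- bcpnn_ic(100, 900, 9900, 89100)
  expect_lt(abs(ind$ic), 0.05)
  # a = 0 with nonzero margins shrinks below independence
  expect_lt(bcpnn_ic(0, 100, 100, 9800)$ic, 0)
})

test_that("the shrinker posterior matches the closed-form gamma case", {
  # degenerate prior P=1, Gamma(1,1): posterior for a=5, E=1 is Gamma(6,2);
  # EBGM = exp(psi(6) - ln 2), EBGM05 = gamma quantile
  prior <- gps_prior(1, 1, 1, 1, 1)
  expect_true(prior$P == 1)
  out <- gps_ebgm(5, 1, prior)
  expect_equal(out$ebgm, exp(digamma(6) - log(2)), tolerance = 1e-10)
  expect_equal(out$ebgm05, stats::qgamma(0.05, 6, rate = 2),
               tolerance = 1e-8)
  expect_equal(round(out$ebgm, 3), 2.754)
  expect_equal(round(out$ebgm05, 2), 1.31)
})

test_that("the mixture posterior matches a quadrature oracle within 1e-4", {
  prior <- gps_prior(0.3, 0.5, 0.3, 2, 4)
  for (case in list(c(a = 7, E = 2), c(a = 0, E = 1.5), c(a = 40, E = 6))) {
    a <- unname(case["a"]); E <- unname(case["E"])
    out <- gps_ebgm(a, E, prior)
    f1 <- stats::dnbinom(a, size = 0.5, prob = 0.3 / (0.3 + E))
    f2 <- stats::dnbinom(a, size = 2, prob = 4 / (4 + E))
    Q <- 0.3 * f1 / (0.3 * f1 + 0.7 * f2)
    # trapezoid quadrature on the log axis
    u <- seq(log(1e-9), log(1e5), length.out = 200001)
    x <- exp(u)
    g <- (Q * stats::dgamma(x, 0.5 + a, rate = 0.3 + E) +
            (1 - Q) * stats::dgamma(x, 2 + a, rate = 4 + E)) * x
    h <- u[2] - u[1]
    w <- rep(h, length(u)); w[c(1, length(u))] <- h / 2
    elog <- sum(u * g * w) / sum(g * w)
    expect_lt(abs(out$ebgm - exp(elog)), 1e-4)
    # posterior CDF at the reported 5th percentile is 0.05
    cdf <- Q * stats::pgamma(out$ebgm05, 0.5 + a, rate = 0.3 + E) +
      (1 - Q) * stats::pgamma(out$ebgm05, 2 + a, rate = 4 + E)
    expect_equal(cdf, 0.05, tolerance = 1e-6)
  }
  # a = 0: shrunk below 1 and the lower bound stays below the mean
  z <- gps_ebgm(0, 1, prior)
  expect_lt(z$ebgm, 1)
  expect_lt(z$ebgm05, z$ebgm)
})

test_that("hyperparameter fitting recovers a single-gamma truth", {
  set.seed(8)
  n <- 5000
  E <- stats::runif(n, 0.5, 20)
  lam <- stats::rgamma(n, shape = 2, rate = 4)
  a <- stats::rpois(n, lam * E)
  prior <- gps_fit(a, E)
  # the dominant component carries the single-gamma truth within 20%
  if (prior$P >= 0.5) {
    shape <- prior$alpha1; rate <- prior$beta1
  } else {
    shape <- prior$alpha2; rate <- prior$beta2
  }
  expect_gt(shape, 2 * 0.8); expect_lt(shape, 2 * 1.2)
  expect_gt(rate, 4 * 0.8); expect_lt(rate, 4 * 1.2)
})

test_that("degenerate and undersized shrinker inputs are handled", {
  expect_error(gps_fit(3, 1.5), "at least 2")
  z <- gps_fit(c(0, 0, 0, 0), c(1, 2, 3, 4))
  expect_true(z$degenerate)
})

test_that("all four statistics are monotone in a with the margins fixed", {
  prior <- gps_prior(0.3, 0.5, 0.3, 2, 4)
  b <- 500; c <- 300; d <- 9000
  a <- 0:30
  ror <- ror_ci(a, b, c, d)$ror
  prr <- prr_chi2(a, b, c, d)$prr
  ic <- bcpnn_ic(a, b, c, d)$ic
  eb <- gps_ebgm(a, rep(2, length(a)), prior)$ebgm
  expect_true(all(diff(ror) > 0))
  expect_true(all(diff(prr) > 0))
  expect_true(all(diff(ic) > 0))
  expect_true(all(diff(eb) > 0))
})

test_that("shrinkage pulls the raw rates toward the null", {
  prior <- gps_prior(0.3, 0.5, 0.3, 2, 4)
  for (case in list(c(5, 1), c(20, 4), c(8, 2))) {
    a <- case[1]; E <- case[2]
    eb <- gps_ebgm(a, E, prior)$ebgm
    expect_gt(eb, 1)
    expect_lt(eb, a / E)
  }
  # IC stays finite and bounded where the raw log2 ratio diverges or is
  # unstable: an empty cell has finite negative IC while raw is -Inf;
  # deficient cells are pulled toward 0; supported cells are inflated by
  # at most the joint prior pseudo-count (log2((a+1)/a))
  expect_true(is.finite(bcpnn_ic(0, 200, 500, 99300)$ic))
  a <- 10; b <- 9990; c <- 2000; d <- 988000
  n <- a + b + c + d
  raw <- log2(a * n / ((a + b) * (a + c)))
  ic <- bcpnn_ic(a, b, c, d)$ic
  expect_lt(raw, 0)
  expect_lt(abs(ic), abs(raw))
  for (case in list(c(3, 197, 3, 99797), c(5, 995, 50, 98950))) {
    a <- case[1]; b <- case[2]; c <- case[3]; d <- case[4]
    n <- a + b + c + d
    raw <- log2(a * n / ((a + b) * (a + c)))
    ic <- bcpnn_ic(a, b, c, d)$ic
    expect_gt(ic, raw)
    expect_lt(ic, raw + log2((a + 1) / a))
  }
})

test_that("classification reproduces the printed positivity patterns", {
  # all-positive row: haematemesis-like metrics
  pos <- data.frame(term = "Haematemesis", a = 106, ror = 14.52,
                    ror_lower = 11.99, ror_upper = 17.58, prr = 14.43,
                    chi2 = 1319.52, ic = 3.84, ic025 = 3.56, ebgm = 14.37,
                    ebgm05 = 12.24)
  out <- classify_signals(pos)
  expect_true(all(out$ror_pos, out$prr_pos, out$bcpnn_pos, out$mgps_pos))
  expect_identical(out$consensus, 4L)
  expect_true(out$robust)
  # all-negative row: dyspnoea-like metrics
  neg <- data.frame(term = "Dyspnoea", a = 136, ror = 0.84,
                    ror_lower = 0.71, ror_upper = 1.00, prr = 0.84,
                    chi2 = 3.95, ic = -0.24, ic025 = -0.49, ebgm = 0.84,
                    ebgm05 = 0.73)
  out2 <- classify_signals(neg)
  expect_identical(out2$consensus, 0L)
  expect_false(out2$positive)
  # minimum-case rule: lower bound above 1 but only 2 cases
  few <- data.frame(term = "x", a = 2, ror = 9, ror_lower = 1.01,
                    ror_upper = 80, prr = 9, chi2 = 12, ic = 1, ic025 = -1,
                    ebgm = 2, ebgm05 = 0.5)
  expect_false(classify_signals(few)$ror_pos)
  expect_false(classify_signals(few)$prr_pos)
})

test_that("classification agrees with a brute-force restatement of the criteria", {
  tabs <- local({
    g <- small_db()
    dd <- deduplicate_reports(g$data)
    tab <- build_event_table(dd)
    build_contingency(tab$reports, tab$events, "pt")
  })
  m <- compute_signal_metrics(tabs)
  expect_identical(m$ror_pos,
                   !is.na(m$ror_lower) & m$ror_lower > 1 & m$a >= 3)
  expect_identical(m$prr_pos,
                   !is.na(m$prr) & m$prr >= 2 & !is.na(m$chi2) &
                     m$chi2 >= 4 & m$a >= 3)
  expect_identical(m$bcpnn_pos, m$ic025 > 0)
  expect_identical(m$mgps_pos, m$ebgm05 > 2)
  expect_identical(m$consensus,
                   m$ror_pos + m$prr_pos + m$bcpnn_pos + m$mgps_pos)
  # interval orderings
  expect_true(all(m$ror_lower <= m$ror & m$ror <= m$ror_upper))
  expect_true(all(m$ic025 <= m$ic))
  expect_true(all(m$ebgm05 <= m$ebgm + 1e-9))
})

test_that("the consensus partition accounts for every positive term", {
  g <- small_db()
  dd <- deduplicate_reports(g$data)
  tab <- build_event_table(dd)
  m <- compute_signal_metrics(build_contingency(tab$reports, tab$events,
                                                "pt"))
  v <- consensus_venn(m)
  expect_identical(sum(v$by_exactly), v$any_positive)
  # all-negative input gives all-zero counts
  m0 <- m
  m0$ror_pos <- m0$prr_pos <- m0$bcpnn_pos <- m0$mgps_pos <- FALSE
  m0$consensus <- 0L
  v0 <- consensus_venn(m0)
  expect_identical(unname(v0$per_algorithm), rep(0L, 4))
  expect_identical(v0$any_positive, 0L)
  # constructed four-way positive
  m1 <- m0[1, ]
  m1$ror_pos <- m1$prr_pos <- m1$bcpnn_pos <- m1$mgps_pos <- TRUE
  m1$consensus <- 4L
  expect_identical(unname(consensus_venn(m1)$by_exactly[4]), 1L)
})
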