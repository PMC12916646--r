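# Time-to-onset: extraction, summaries, parametric MLE against grid-search
# and external oracles, AIC selection consistency, hazard labels, strata.

test_that("TTO is the day difference from earliest target start to event", {
  db <- toy_db()
  db$demo$event_dt[db$demo$primaryid == "1"] <- "20230108"
  out <- extract_tto(db, c("ARIXTRA", "FONDAPARINUX SODIUM"))
  expect_identical(out$sample$days[out$sample$primaryid == "1"], 7)
  # report 3/4 have no target drug therapy rows -> excluded as missing start
  expect_true(all(c("3", "4") %in% out$exclusions$primaryid))
  expect_identical(unique(out$exclusions$reason[
    out$exclusions$primaryid %in% c("3", "4")]), "missing_start")
  # blank the start date of report 2
  db$ther$start_dt[db$ther$primaryid == "2"] <- ""
  out2 <- extract_tto(db, c("ARIXTRA", "FONDAPARINUX SODIUM"))
  expect_identical(out2$exclusions$reason[out2$exclusions$primaryid == "2"],
                   "missing_start")
  # partial event date
  db$demo$event_dt[db$demo$primaryid == "1"] <- "202301"
  out3 <- extract_tto(db, c("ARIXTRA", "FONDAPARINUX SODIUM"))
  expect_identical(out3$exclusions$reason[out3$exclusions$primaryid == "1"],
                   "partial_event")
})

test_that("date missingness propagates to the extracted sample size", {
  g <- small_db()
  dd <- deduplicate_reports(g$data)
  cohort <- filter_primary_suspect(dd)
  out <- extract_tto(cohort)
  n_cohort <- nrow(cohort$demo)
  # 61% missing plus 5% partial degradation: usable fraction ~ 0.37
  frac <- nrow(out$sample) / n_cohort
  expect_gt(frac, 0.25)
  expect_lt(frac, 0.48)
  expect_identical(nrow(out$sample) + nrow(out$exclusions), n_cohort)
})

test_that("the summary uses interpolation quantiles and closed bins", {
  s <- summarize_tto(1:10)
  expect_equal(s$median, 5.5)
  expect_equal(c(s$q1, s$q3), c(3.25, 7.75))
  expect_identical(unname(s$bins["0-7"]), 7L)
  expect_identical(unname(s$bins["8-30"]), 3L)
  expect_equal(s$prop_7d, 0.7)
  expect_equal(s$prop_30d, 1)
  # degenerate sample
  s7 <- summarize_tto(rep(7, 5))
  expect_equal(s7$median, 7)
  expect_equal(s7$prop_7d, 1)
  # extreme value lands in the open top bin
  expect_identical(unname(summarize_tto(400)$bins[">360"]), 1L)
  expect_error(summarize_tto(numeric(0)), "empty")
})

test_that("large-sample MLE recovers the generating log-logistic parameters", {
  set.seed(42)
  t <- rloglogistic(50000, scale = 7.8, shape = 1.2)
  f <- fit_tto(t, "loglogistic")
  expect_lt(abs(f$estimate["scale"] - 7.8), 0.1)
  expect_lt(abs(f$estimate["shape"] - 1.2), 0.02)
  expect_equal(f$aic, 4 - 2 * f$loglik)
})

test_that("the fitted log-logistic scale is the model median exactly", {
  set.seed(10)
  t <- rloglogistic(500, scale = 12, shape = 0.9)
  f <- fit_tto(t, "loglogistic")
  expect_equal(ploglogistic(f$estimate[["scale"]],
                            scale = f$estimate[["scale"]],
                            shape = f$estimate[["shape"]]), 0.5)
  expect_equal(qloglogistic(0.5, f$estimate[["scale"]],
                            f$estimate[["shape"]]),
               f$estimate[["scale"]])
})

test_that("the optimizer is never beaten by a grid search of the likelihood", {
  set.seed(3)
  t <- rloglogistic(100, scale = 7.8, shape = 1.2)
  for (fam in c("weibull", "loglogistic", "lognormal")) {
    f <- fit_tto(t, fam)
    nll <- pvsignal:::tto_nll(fam)
    scales <- seq(f$estimate["scale"] * 0.5, f$estimate["scale"] * 2,
                  length.out = 200)
    shapes <- seq(f$estimate["shape"] * 0.5, f$estimate["shape"] * 2,
                  length.out = 200)
    grid_best <- min(vapply(scales, function(sc)
      min(vapply(shapes, function(sh) nll(c(sc, sh), t), numeric(1))),
      numeric(1)))
    expect_lt(-f$loglik, grid_best + 1e-3)
  }
})

test_that("in-package densities agree with external survival parameterizations", {
  skip_if_not_installed("flexsurv")
  x <- c(0.5, 1, 5, 20, 100)
  expect_equal(dloglogistic(x, scale = 7.8, shape = 1.2),
               flexsurv::dllogis(x, scale = 7.8, shape = 1.2),
               tolerance = 1e-12)
  expect_equal(ploglogistic(x, scale = 7.8, shape = 1.2),
               flexsurv::pllogis(x, scale = 7.8, shape = 1.2),
               tolerance = 1e-12)
})

test_that("MLE agrees with fitdistrplus on lognormal and weibull", {
  skip_if_not_installed("fitdistrplus")
  set.seed(6)
  t <- rlnorm(800, meanlog = 2, sdlog = 0.8)
  f <- fit_tto(t, "lognormal")
  oracle <- fitdistrplus::fitdist(t, "lnorm")
  expect_equal(log(f$estimate[["scale"]]),
               unname(oracle$estimate["meanlog"]), tolerance = 1e-4)
  expect_equal(f$estimate[["shape"]], unname(oracle$estimate["sdlog"]),
               tolerance = 1e-4)
  fw <- fit_tto(t, "weibull")
  ow <- fitdistrplus::fitdist(t, "weibull")
  expect_equal(fw$estimate[["scale"]], unname(ow$estimate["scale"]),
               tolerance = 1e-3)
  expect_equal(fw$estimate[["shape"]], unname(ow$estimate["shape"]),
               tolerance = 1e-3)
})

test_that("zero-day onsets are shifted to half a day and counted", {
  t <- c(rep(0, 4), rloglogistic(60, 7, 1.2))
  f <- fit_tto(t, "loglogistic")
  expect_identical(f$n_zero_adjusted, 4L)
  expect_error(fit_tto(rep(1, 5), "weibull"), "at least 10")
})

test_that("AIC selection is consistent at the study sample size", {
  # seeded replicates at n = 2,220 from the early-peak log-logistic model:
  # the generating family must win the AIC ranking in >= 80% of runs
  set.seed(123)
  wins <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    t <- rloglogistic(2220, scale = 7.8, shape = 1.2)
    fits <- lapply(c("weibull", "loglogistic", "lognormal"),
                   function(fam) fit_tto(t, fam))
    if (aic_select(fits)$best$family == "loglogistic") wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.8)
})

test_that("AIC selection validates its inputs and breaks ties predictably", {
  set.seed(2)
  t <- rloglogistic(200, 7, 1.2)
  f1 <- fit_tto(t, "loglogistic")
  expect_error(aic_select(list(f1)), "at least two")
  f_other <- fit_tto(rloglogistic(200, 7, 1.2), "weibull")
  expect_error(aic_select(list(f1, f_other)), "different samples")
  # identical log-likelihoods break ties lexicographically
  f2 <- fit_tto(t, "weibull")
  f2$loglik <- f1$loglik
  f2$aic <- f1$aic
  sel <- aic_select(list(f2, f1))
  expect_identical(sel$best$family, "loglogistic")
})

test_that("hazard patterns follow the shape thresholds", {
  fake_fit <- function(family, shape) {
    structure(list(family = family,
                   estimate = c(scale = 7, shape = shape)),
              class = "tto_fit")
  }
  expect_identical(hazard_pattern(fake_fit("loglogistic", 1.2)),
                   "early peak")
  expect_identical(hazard_pattern(fake_fit("loglogistic", 0.9)),
                   "monotone decreasing")
  expect_identical(hazard_pattern(fake_fit("weibull", 1)), "random")
  expect_identical(hazard_pattern(fake_fit("weibull", 0.7)),
                   "early failure")
  expect_identical(hazard_pattern(fake_fit("weibull", 1.7)), "wear-out")
  expect_identical(hazard_pattern(fake_fit("lognormal", 1)), "unimodal")
})

test_that("cluster summaries partition correctly and recover distinct medians", {
  # two disjoint clusters with different generating medians
  set.seed(9)
  n <- 500L
  days_a <- rloglogistic(n, scale = 7, shape = 2.5)
  days_b <- rloglogistic(n, scale = 5.5, shape = 2.5)
  sample <- data.frame(primaryid = as.character(seq_len(2 * n)),
                       days = c(days_a, days_b))
  events <- data.frame(primaryid = sample$primaryid,
                       pt = rep(c("Haematoma", "Rash"), each = n))
  out <- stratified_tto(sample, events,
                        list(bleeding = "Haematoma", rash = "Rash"))
  expect_identical(out$n, c(2L * n, n, n))
  expect_lt(abs(out$median[out$cluster == "bleeding"] - 7), 1)
  expect_lt(abs(out$median[out$cluster == "rash"] - 5.5), 1)
  # single-value cluster and empty cluster
  one <- stratified_tto(data.frame(primaryid = "1", days = 5),
                        data.frame(primaryid = "1", pt = "Rash"),
                        list(rash = "Rash", bleeding = "Haematoma"))
  expect_equal(one$median[one$cluster == "rash"], 5)
  expect_equal(one$prop_7d[one$cluster == "rash"], 1)
  expect_identical(one$n[one$cluster == "bleeding"], 0L)
  expect_true(is.na(one$median[one$cluster == "bleeding"]))
})

test_that("parameter recovery and interval coverage hold across seeds", {
  set.seed(77)
  reps <- 60L
  scales <- numeric(reps); shapes <- numeric(reps)
  cov_scale <- 0L; cov_shape <- 0L
  for (r in seq_len(reps)) {
    t <- rloglogistic(2220, scale = 7.8, shape = 1.2)
    f <- fit_tto(t, "loglogistic")
    scales[r] <- f$estimate["scale"]; shapes[r] <- f$estimate["shape"]
    if (f$ci["scale", 1] <= 7.8 && f$ci["scale", 2] >= 7.8)
      cov_scale <- cov_scale + 1L
    if (f$ci["shape", 1] <= 1.2 && f$ci["shape", 2] >= 1.2)
      cov_shape <- cov_shape + 1L
  }
  expect_lt(abs(mean(scales) - 7.8) / 7.8, 0.02)
  expect_lt(abs(mean(shapes) - 1.2) / 1.2, 0.02)
  expect_gte(cov_scale / reps, 0.90)
  expect_gte(cov_shape / reps, 0.85)
})
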