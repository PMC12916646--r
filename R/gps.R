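# DuMouchel's gamma-Poisson shrinker (MGPS).
#
# Model: the count a in each drug-event cell is Poisson(lambda * E) with
# baseline expectation E = (a+b)(a+c)/N and relative reporting rate lambda
# drawn from a two-component gamma mixture prior
#   lambda ~ P * Gamma(alpha1, beta1) + (1-P) * Gamma(alpha2, beta2)
# (shape/rate). Marginally a is a mixture of negative binomials; the five
# hyperparameters are fitted by maximizing the marginal likelihood over all
# cells of the database. Posterior summaries shrink the raw a/E toward 1.

#' Construct a gamma-Poisson shrinker prior
#'
#' @param P mixture weight of the first gamma component, in (0, 1].
#' @param alpha1,beta1,alpha2,beta2 shape/rate of the two gamma components
#'   (all > 0).
#' @param loglik optional fitted marginal log-likelihood.
#' @param degenerate flag for collapsed fits (boundary weight or
#'   indistinguishable components).
#' @return object of class `gps_prior`.
#' @export
gps_prior <- function(P, alpha1, beta1, alpha2, beta2, loglik = NA_real_,
                      degenerate = FALSE) {
  stopifnot(P > 0, P <= 1, alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0)
  structure(list(P = P, alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, loglik = loglik, degenerate = degenerate),
            class = "gps_prior")
}

#' @export
print.gps_prior <- function(x, ...) {
  cat(sprintf(
    "<gps_prior> P=%.4f  Gamma1(shape=%.4f, rate=%.4f)  Gamma2(shape=%.4f, rate=%.4f)\n",
    x$P, x$alpha1, x$beta1, x$alpha2, x$beta2))
  if (!is.na(x$loglik)) cat(sprintf("  marginal loglik: %.4f\n", x$loglik))
  if (x$degenerate) cat("  (degenerate fit)\n")
  invisible(x)
}

gps_marginal_nll <- function(par, a, E) {
  # par on transformed scale: log shapes/rates, logit mixture weight
  a1 <- exp(par[1]); b1 <- exp(par[2])
  a2 <- exp(par[3]); b2 <- exp(par[4])
  P <- stats::plogis(par[5])
  l1 <- log(P) + stats::dnbinom(a, size = a1, prob = b1 / (b1 + E),
                                log = TRUE)
  l2 <- log1p(-P) + stats::dnbinom(a, size = a2, prob = b2 / (b2 + E),
                                   log = TRUE)
  m <- pmax(l1, l2)
  -sum(m + log(exp(l1 - m) + exp(l2 - m)))
}

#' Fit the gamma-Poisson shrinker hyperparameters
#'
#' Maximizes the marginal (negative-binomial mixture) likelihood over all
#' supplied cells by quasi-Newton optimization on transformed parameters,
#' starting from the conventional point (alpha1 = 0.2, beta1 = 0.1,
#' alpha2 = 2, beta2 = 4, P = 1/3) with perturbed multi-start fallbacks.
#'
#' @param a integer vector of observed cell counts (>= 2 cells).
#' @param E numeric vector of baseline expected counts (> 0).
#' @param starts optional list of numeric start vectors
#'   `c(alpha1, beta1, alpha2, beta2, P)`.
#' @param tol convergence tolerance on the log-likelihood.
#' @return a [gps_prior()]; fits where every count is zero or the mixture
#'   collapses carry `degenerate = TRUE`. If no start converges an error is
#'   raised carrying the best iterate.
#' @export
gps_fit <- function(a, E, starts = NULL, tol = 1e-6) {
  stopifnot(length(a) == length(E), all(E > 0), all(a >= 0))
  if (length(a) < 2L) {
    stop("gps_fit requires at least 2 contingency cells", call. = FALSE)
  }
  if (all(a == 0)) {
    return(gps_prior(1 / 3, 0.2, 0.1, 2, 4, loglik = NA_real_,
                     degenerate = TRUE))
  }
  if (is.null(starts)) {
    base <- c(0.2, 0.1, 2, 4, 1 / 3)
    starts <- list(base,
                   c(1, 1, 1, 1, 0.5),
                   c(0.5, 0.5, 4, 2, 0.2),
                   c(2, 4, 0.2, 0.1, 0.667))
  }
  best <- NULL
  for (s in starts) {
    par0 <- c(log(s[1:4]), stats::qlogis(s[5]))
    # box constraints keep the mixture away from point-mass collapse,
    # which the marginal likelihood can reward on small databases
    fit <- tryCatch(
      stats::optim(par0, gps_marginal_nll, a = a, E = E,
                   method = "L-BFGS-B",
                   lower = c(rep(-10, 4), -7), upper = c(rep(10, 4), 7),
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("gps_fit: no start converged", call. = FALSE)
  }
  if (best$convergence != 0) {
    cond <- simpleError("gps_fit: optimizer failed to converge from all starts")
    cond$best_iterate <- best
    stop(cond)
  }
  p <- best$par
  a1 <- exp(p[1]); b1 <- exp(p[2]); a2 <- exp(p[3]); b2 <- exp(p[4])
  P <- stats::plogis(p[5])
  collapse <- (abs(log(a1 / a2)) < 1e-3 && abs(log(b1 / b2)) < 1e-3) ||
    P < 1e-4 || P > 1 - 1e-4 || max(a1, b1, a2, b2) > exp(10) * 0.99
  gps_prior(P, a1, b1, a2, b2, loglik = -best$value, degenerate = collapse)
}

#' Empirical Bayes geometric mean and its 5th posterior percentile
#'
#' Given the fitted prior, the posterior of the relative reporting rate for
#' a cell with count `a` and expectation `E` is again a two-gamma mixture
#' with updated weights. EBGM = `2^E[log2 lambda | a]` (geometric mean of
#' the posterior) and EBGM05 is the 5th percentile of the posterior mixture
#' CDF, found by bracketed root-finding.
#'
#' @param a,E observed counts and baseline expectations (vectors).
#' @param prior a [gps_prior()].
#' @param p percentile for the lower bound (0.05).
#' @param tol root-finding tolerance.
#' @return data.frame with columns `ebgm`, `ebgm05`.
#' @export
gps_ebgm <- function(a, E, prior, p = 0.05, tol = 1e-8) {
  stopifnot(inherits(prior, "gps_prior"), length(a) == length(E),
            all(E > 0))
  a1 <- prior$alpha1 + a; b1 <- prior$beta1 + E
  a2 <- prior$alpha2 + a; b2 <- prior$beta2 + E
  if (prior$P >= 1) {
    Q <- rep(1, length(a))
  } else {
    # posterior component weights in log space to avoid underflow at large a
    l1 <- log(prior$P) + stats::dnbinom(a, size = prior$alpha1,
                                        prob = prior$beta1 / (prior$beta1 + E),
                                        log = TRUE)
    l2 <- log1p(-prior$P) + stats::dnbinom(a, size = prior$alpha2,
                                           prob = prior$beta2 / (prior$beta2 + E),
                                           log = TRUE)
    Q <- stats::plogis(l1 - l2)
  }
  elog <- Q * (digamma(a1) - log(b1)) + (1 - Q) * (digamma(a2) - log(b2))
  ebgm <- exp(elog)
  cdf <- function(x, i) {
    Q[i] * stats::pgamma(x, shape = a1[i], rate = b1[i]) +
      (1 - Q[i]) * stats::pgamma(x, shape = a2[i], rate = b2[i])
  }
  ebgm05 <- vapply(seq_along(a), function(i) {
    if (Q[i] > 1 - 1e-12) {
      return(stats::qgamma(p, shape = a1[i], rate = b1[i]))
    }
    if (Q[i] < 1e-12) {
      return(stats::qgamma(p, shape = a2[i], rate = b2[i]))
    }
    q1 <- stats::qgamma(p, shape = a1[i], rate = b1[i])
    q2 <- stats::qgamma(p, shape = a2[i], rate = b2[i])
    lo <- min(q1, q2); hi <- max(q1, q2)
    if (hi - lo < tol) return(lo)
    stats::uniroot(function(x) cdf(x, i) - p, lower = lo, upper = hi,
                   tol = tol, extendInt = "yes")$root
  }, numeric(1))
  data.frame(ebgm = ebgm, ebgm05 = ebgm05)
}
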