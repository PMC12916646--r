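# pvsignal

Disproportionality signal detection and time-to-onset modelling for
spontaneous adverse-event reports.

Post-marketing drug safety surveillance rests on spontaneous reporting
systems (SRS) such as FAERS: large collections of voluntary reports in
which a drug–event pair's reporting frequency can be compared against the
database background. `pvsignal` is for pharmacoepidemiologists and
pharmacovigilance analysts who need that workflow end to end, reproducibly:
FAERS-dialect ingestion and case-version deduplication, primary-suspect
cohort selection, 2×2 contingency tables at MedDRA PT and SOC level, four
disproportionality algorithms with the standard positivity thresholds,
subgroup and co-medication sensitivity re-analysis, and parametric
time-to-onset modelling. A synthetic SRS generator with known ground truth
makes every stage testable offline.

## Methods at a glance

For each drug–event pair the 2×2 table (a, b, c, d; N = a+b+c+d,
E = (a+b)(a+c)/N) feeds four statistics:

- **ROR** = ad/bc, 95% CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`;
  positive when the lower bound exceeds 1 with a ≥ 3.
- **PRR** = [a/(a+b)]/[c/(c+d)] with the Pearson χ²; positive when
  PRR ≥ 2, χ² ≥ 4 and a ≥ 3.
- **BCPNN IC** = log₂ p(drug, event)/(p(drug)·p(event)) under conjugate
  Beta posteriors (exact posterior moments, prior calibrated to E[IC] = 0);
  positive when IC025 > 0.
- **MGPS EBGM**: a ~ Poisson(λE) with a fitted two-gamma mixture prior on
  λ (DuMouchel's gamma-Poisson shrinker); EBGM = 2^E[log₂ λ | a], EBGM05
  its 5th posterior percentile; positive when EBGM05 > 2.

A term is *positive* when at least one criterion holds and *robust* when
all four do. Time-to-onset (days from first target-drug administration to
event) is fitted by maximum likelihood under Weibull, log-logistic and
log-normal models; the lowest AIC wins, and the shape parameter labels the
hazard (log-logistic shape > 1 ⇒ unimodal "early peak").

## Worked example

Generate a synthetic database with two injected signals and run the full
study:

```r
library(pvsignal)

cfg <- srs_config(
  n_reports = 10000,
  injected_signals = data.frame(pt = c("Haematemesis", "Skin necrosis"),
                                rr = c(10, 8)),
  seed = 20261001)
g <- generate_srs(cfg)
res <- run_full_analysis(g$data)
res
#> <pv_analysis>
#>   cohort: 462 target reports in a database of 10000
#>   PT terms tabulated: 169 (positive: 12, robust: 2)
#>   TTO: n=156, median 7.0 d, best family lognormal (unimodal)
#>   config hash: 9f8c99502494a76223d964ce87fd23bb

head(format_signal_table(
  res$signals_pt[order(-res$signals_pt$consensus, -res$signals_pt$a), ]), 5)
#>           term   n                   ror                  prr    chi2         ebgm           ic consensus
#>   Haematemesis 361 44.78* (35.45, 56.57) 10.57* (9.70, 11.52) 2315.86 7.17* (6.62) 2.87* (2.66)         4
#>  Skin necrosis  88   8.53* (6.56, 11.10)   7.10* (5.68, 8.87)  355.22 5.92* (5.19) 2.47* (2.12)         4
#>        PT_0044   8    2.88* (1.37, 6.07)   2.85* (1.37, 5.93)    8.48  1.03 (1.01) 1.47* (0.43)         3
#>        PT_0048   7    2.24* (1.02, 4.92)   2.22* (1.03, 4.82)    4.28  1.03 (1.01) 1.16* (0.07)         3
#>        PT_0053   7    3.95* (1.75, 8.91)   3.91* (1.75, 8.71)   12.78  1.20 (1.01) 1.87* (0.74)         3
```

Both injected terms — and only they — reach four-algorithm consensus
("robust"); the remaining low-count positives show the expected behaviour
of threshold criteria on borderline cells (note how the shrinker pulls
their EBGM back to ~1 while the unshrunk ROR/PRR flag them). The starred
entries mark each algorithm's criterion; intervals are in parentheses,
with EBGM05 and IC025 as the single parenthesised bounds.

```r
res$tto$selection$ranking
#>       family    loglik      aic rank
#>    lognormal -565.8604 1135.721    1
#>  loglogistic -569.0186 1142.037    2
#>      weibull -578.7877 1161.575    3
```

At this TTO sample size (n = 156 after 61% date missingness) the
log-normal and log-logistic fits are nearly equivalent — both imply a
unimodal early-peaking hazard with median onset around a week; the AIC
ranking separates the generating family reliably at cohort-scale samples
(n ≈ 2,200), which the test suite checks across seeded replicates.

Subgroup tables (`res$subgroups`), the co-medication sensitivity
comparison (`res$sensitivity$persistence`) and the stage-by-stage record
manifest (`res$manifest`) are part of the same result object, and
`write_faers_quarter()` / `read_faers_quarter()` round-trip databases
through the '$'-delimited quarterly file dialect.

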