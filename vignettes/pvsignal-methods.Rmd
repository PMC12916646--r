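---
title: "Disproportionality signal detection and time-to-onset modelling with pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection and time-to-onset modelling with pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pvsignal implements a complete post-marketing pharmacovigilance workflow
for spontaneous reporting system (SRS) data: ingestion of FAERS-dialect
quarterly files, case-version deduplication, primary-suspect cohort
selection, four-algorithm disproportionality analysis at the MedDRA
Preferred Term (PT) and System Organ Class (SOC) level, subgroup and
co-medication sensitivity re-analysis, and parametric time-to-onset (TTO)
modelling. This vignette is the package's account of the statistical
methods, the choices that were genuinely open, and what the bundled
synthetic-data generator does and does not establish.

## The data model and cohort rules

An SRS database is four relational character tables keyed by `PRIMARYID`:
demographics (`DEMO`), drugs with role codes (`DRUG`), reactions as PTs
(`REAC`) and therapy dates (`THER`). All columns stay character through
ingestion so partial dates (`YYYYMM`, `YYYY`) and blanks survive file
round-trips.

**Deduplication.** SRS cases are resubmitted as new versions under a
shared `CASEID`. For each case the version with the latest `FDA_DT` is
kept, ties broken by the higher `PRIMARYID`. The operation is
deterministic (output sorted by `PRIMARYID`) and idempotent, both of
which are tested.

**Cohort selection.** The analysis cohort is the set of reports naming
the target drug — matched exactly against a synonym list after trimming,
whitespace collapsing and case folding — with role code `PS` (primary
suspect). Secondary-suspect and concomitant entries never qualify. Exact
matching was chosen over fuzzy matching deliberately: reproducibility
over recall; a missed spelling variant belongs in the synonym list, not
in an edit-distance heuristic.

**Indication bias.** PTs describing the treated condition itself can
masquerade as drug reactions (confounding by indication). A user-supplied
exclusion list is removed from the cohort's event lists; reports left
eventless are dropped and counted. The exclusion is applied cohort-side
only — a term absent from the cohort is simply never tabulated — because
2x2 tables are only built for terms with at least one cohort report.

**Date audit.** Reports whose event date strictly precedes the earliest
target-drug therapy start are excluded with a reason code. Two partial
dates are compared only at their shared precision, and equality at that
precision is non-violating. This is deliberately conservative: a manual
audit of individual records cannot be automated, so the automatic rule
only excludes records that are provably inconsistent at the recorded
precision.

**Missing demographics.** Reports missing age or sex can either be kept
as an explicit `missing` stratum (the default, which keeps the
demographic composition tables complete) or removed via
`drop_missing_demographics = TRUE` (the strict reading of a
complete-case cohort rule). Both are defensible; the switch makes the
choice visible in the configuration rather than implicit in the code.

## 2x2 tables

For each event term within a stratum,

|                | event | no event |
|----------------|-------|----------|
| target drug    | a     | b        |
| all other drugs| c     | d        |

with report-level counting: a report contributes at most once to a cell
for a given term, and at SOC level one or more PTs of the SOC count
once. The background comparator is the rest of the supplied database —
the standard design when no external comparator is stated. The
minimum-case rule (a >= 3) is applied at classification time, not at
tabulation, so rare terms remain inspectable.

## The four algorithms

**ROR.** `ad/bc` with the log-normal interval
`exp(ln ROR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. A zero cell triggers
the Haldane–Anscombe +0.5 correction on all four cells, flagged in the
output; the published formula stays exact on nonzero tables.

**PRR.** `[a/(a+b)] / [c/(c+d)]` with the Pearson chi-square of the
table. No continuity correction by default — the common SRS convention —
with a `yates` switch. A PRR interval (log-normal standard error
`sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d))`) is reported for completeness but
feeds no criterion.

**BCPNN information component.** IC = log2 of the joint reporting
probability over the product of its margins, under independent conjugate
Beta posteriors with marginal priors `Beta(1, 1)` against totals
`alpha = beta = 2`, and the joint prior count chosen so the prior IC
expectation is zero. The point estimate is the *exact* posterior mean
(digamma form) and the posterior variance is exact (trigamma form); the
credibility bound is the normal approximation IC − 1.96 SD (a 2-SD
legacy variant is available via `ic_z = 2`). The exact-moment form was
chosen over the older log-of-expectation approximation because the
package's correctness anchor is a Monte-Carlo sample of the conjugate
posterior, and the approximation is off by ~0.05 bits on reference
tables — more than the 0.02-bit agreement the test suite demands. One
consequence worth knowing: on supported cells the posterior mean sits
slightly *above* the raw log2 ratio (the joint prior contributes roughly
half a pseudo-count to `a`); genuine shrinkage shows on deficient and
empty cells, where the raw ratio is unstable or divergent and the IC
stays finite — exactly the regime shrinkage is for.

**Gamma-Poisson shrinker (MGPS).** Counts are modelled as
`a ~ Poisson(lambda E)` with `E = (a+b)(a+c)/N` and a two-component
gamma mixture prior on the relative reporting rate lambda. The five
hyperparameters are fitted by maximizing the marginal
negative-binomial-mixture likelihood across all cells of the database,
from the conventional start `(0.2, 0.1, 2, 4, 1/3)` with perturbed
multi-starts. The optimization is box-constrained on log-parameters
(|log| <= 10): on small databases (hundreds of cells rather than the
millions of a full SRS) the unconstrained marginal likelihood rewards
point-mass components, and the bounds keep the fit proper; collapsed
fits are flagged `degenerate`. The posterior per cell is again a
two-gamma mixture with data-updated weights; EBGM is the posterior
geometric mean `2^{E[log2 lambda | a]}` and EBGM05 the 5th posterior
percentile by bracketed root-finding (tolerance 1e-8), verified against
closed-form and quadrature oracles. The shrinker prior is re-fitted per
analysis level and per stratum — each stratum is its own database, so
shrinkage reflects that stratum's background.

**Criteria and consensus.** ROR+ requires the interval's lower bound
above 1 with at least 3 cases; PRR+ requires PRR >= 2, chi-square >= 4
and at least 3 cases; BCPNN+ requires IC025 > 0; MGPS+ requires
EBGM05 > 2. A term is *positive* with at least one flag and *robust*
with all four. No multiple-testing adjustment is applied — these are
fixed-threshold surveillance criteria, not hypothesis tests — and that
is stated in the output metadata rather than silently assumed.

## Sensitivity and subgroups

The sensitivity re-analysis removes whole reports containing any listed
co-medication (default: prednisone, aspirin, hydroxychloroquine) in
*any* role, since "reports involving" a co-therapy is a report-level,
role-agnostic notion. A signal *persists* when it is positive in both
runs and keeps a ROR lower bound above 1 with at least 3 cases after
exclusion. Subgroup tables (sex, age bands `<18` / `18–64` / `>=65` with
65 inclusive on the elderly side, reporter class) are rebuilt from
scratch inside each stratum with a stratum-restricted background, not
filtered from the global table.

## Time-to-onset

TTO is the day difference between the earliest day-precision
target-drug therapy start and the day-precision event date; reports with
missing or partial dates are excluded with reason codes. Where several
therapy rows exist the earliest start is used — the first exposure is
the natural time origin when the per-event linkage is not recorded.

Three two-parameter families are fitted by maximum likelihood, all
parameterized as (scale, shape): Weibull
`F(t) = 1 − exp(−(t/alpha)^beta)`, log-logistic
`F(t) = 1/(1 + (t/alpha)^(−beta))`, and log-normal (scale = exp(mean
log), so the scale is the model median for the log-logistic and
log-normal families). Same-day events (t = 0) are set to 0.5 day and
counted: log-scale likelihoods are undefined at zero, and same-day onset
is real data, not an error. Optimization is quasi-Newton on
log-parameters with a finite barrier at invalid values; 95% Wald
intervals come from the numerically differentiated observed information
at the optimum, which matches the symmetric intervals conventionally
reported for these models. Fits carry a sample fingerprint so AIC
comparison across different samples is an error, not a silent mistake.
Model choice is by lowest AIC (= 4 − 2 loglik for every family here),
ties broken lexicographically. Hazard labels follow the shape parameter:
log-logistic shape > 1 is a unimodal "early peak" hazard, <= 1 monotone
decreasing; Weibull shape below/at/above 1 is early failure / random /
wear-out; log-normal hazards are always unimodal.

Summaries use linear-interpolation quantiles (the standard type-7
definition) and the day bins 0–7, 8–30, 31–60, 61–90, 91–180, 181–360,
>360 with "0–7" meaning t <= 7. Cluster-stratified summaries (e.g.
bleeding vs rash) take a report into a cluster when any of its events is
in the cluster's term list; clusters may overlap. Right-censoring is
out of scope: spontaneous reports record realized onsets only.

## The synthetic generator: what it emulates and what it does not

`generate_srs()` draws desk-scale databases with known ground truth.
Background PT frequencies follow a Zipf law (default exponent 1.1) —
SRS term frequencies are heavy-tailed, and a one-parameter power law is
the simplest faithful background when no background composition is
published. Per report, PT k enters independently with probability
`rate(k)`, multiplied by the configured relative risk for exposed
reports (capped at 1). Duplicates are injected as later case versions
(FDA date + 1–90 days, higher id) so the deduplication rule has a
well-defined correct answer. Dates are emitted as `YYYYMMDD` with a
configurable fraction blanked or degraded to month/year precision.

The defaults are the conditions of the motivating study design:
demographic mixtures matching the observed composition of a real
anticoagulant cohort (34.65/48.51/16.84% male/female/missing;
0.49/27.16/38.26/34.09% across age bands; 50.23/46.96/2.81% across
reporter classes), a mean of 3 events per report, 61% of reports with
unusable therapy/event dates, and TTO clusters following log-logistic
laws — default scale 7.8 days and shape 1.2, with bleeding and rash
clusters at medians 7 and 5.5 days. The default database is 20,000
reports with a 5% target share: large enough that injected tenfold
signals yield stable cells, small enough to generate in seconds. A
real SRS background is three orders of magnitude larger, which is why
published headline RORs against the full database are not reproducible
here; tests therefore validate *recovery of known injected truth* and
*exact arithmetic on printed inputs*, never the headline estimates
themselves.

Features of real data the generator does not emulate: correlated
co-occurrence of PTs within a report beyond shared cluster membership,
indication fields and outcome codes, reporting-culture drift over time,
and country-specific term preferences. Passing tests on synthetic data
therefore establish correctness of the statistical machinery and the
pipeline plumbing, not robustness to every real-world artefact.

## Numerical choices

- GPS marginal likelihood and posterior weights are computed in log
  space (log-sum-exp); posterior weights underflow otherwise once
  a is large.
- EBGM05 root-finding brackets the mixture quantile between the two
  component quantiles; numerically one-component posteriors short-cut
  to the gamma quantile directly.
- Convergence tolerances: 1e-6 on the GPS log-likelihood, 1e-8 for the
  TTO optimizer and the quantile root-finder.
- The chi-square is computed from the determinant form
  `N(ad−bc)^2 / ((a+b)(c+d)(a+c)(b+d))` in double precision (the cell
  products overflow 32-bit integers on realistic tables).
- Problem sizes in the test suite (databases of 4,000–20,000 reports,
  TTO samples of n = 2,220 matching the study cohort, 25–40 seeded
  replicates for selection-consistency checks) were chosen to give
  stable pass/fail behaviour at interactive runtimes.

## Orchestration

`run_full_analysis()` is the single entry point: it executes every stage
in order, records a stage-by-stage manifest of report counts with
removal reasons (flow conservation is a tested invariant: each stage's
count equals the previous minus its logged exclusions), stamps every
output table with an MD5 hash of the configuration, and returns all
intermediate and final tables. Configurations round-trip through YAML.
The package deliberately ships no shell executable: like the
established R packages in this area, the intended interface is the R
function layer, which composes with scripting as needed.
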