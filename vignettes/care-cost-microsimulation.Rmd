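---
title: "Projecting the financial costs of informal mental-health care: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting the financial costs of informal mental-health care: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(caresim)
```

## The model

`caresim` is a static microsimulation: it never simulates individual life
transitions. A base-year person file (working age, 15–64) is carried to
future years purely by re-calibrating its survey weights to projected
population benchmarks ("static ageing"), while the monetary attributes
attached to each record are carried forward by real-growth indexation. On
top of that projected file, the quantity of interest is estimated by a
matched Monte Carlo counterfactual: for each primary carer who is out of
the labour force because of caring for someone with a mental or
behavioural disorder, what would their weekly income, welfare receipts and
tax payments look like if they instead resembled an otherwise-similar
non-carer who is in the labour force?

The pipeline order is fixed: reweight → index → select cohorts → estimate
counterfactuals → aggregate. Reweighting only touches weights and
indexation only touches money, so the first two stages commute; the suite
asserts this equivalence rather than assuming it.

## Synthetic study conditions

Because the survey and tax/transfer files such an analysis really uses are
restricted, the generator in `pop_config()` / `generate_population()` /
`generate_donor_pool()` defines the study conditions for every test and
for the acceptance script. Its defaults are fixed once:

* **Scope constants.** Ages 15–64 in ten 5-year bands; base year 2015; all
  money in 2015 real AU$/week.
* **Carer structure.** 75% of primary carers are women; the share of
  carers out of the labour force because of caring is 12 900/53 700 ≈ 0.24;
  record weights are one constant scaled so the weighted count of
  mental-illness primary carers is exactly 53 700 in the base year.
* **Prevalence choices.** `carer_share = 0.03` and
  `mental_illness_care_share = 0.13` are not published constants of the
  emulated surveys; they are round values in the realistic range for
  working-age primary-carer prevalence and for mental/behavioural
  disorders as the main cared-for condition, and they give base-file
  cohort record counts (tens of qualifying records at the default 50 000)
  of the same order as the small samples such analyses actually rest on.
* **Incomes.** Weekly earned income is lognormal within (labour-force
  status, education, age) cells: positive, right-skewed, two-parameter,
  easy to calibrate. Full-time education-level means (1120, 1380, 1590,
  2056) are chosen so the education-weighted mean plus the mean full-time
  residual benefit (18) equals AU$1544/week for full-time non-carers; the
  life-cycle age profile is normalised to mean one so it does not disturb
  that calibration. Part-time earnings are 45% of full-time;
  the unemployed and those out of the labour force earn zero.
* **Welfare.** Rule-based: carers out of the labour force receive the
  Carer Payment (mean 320); non-carers out of the labour force receive
  the Disability Support Pension with probability 0.35 (mean 340); small
  "other benefits" exist everywhere (means 18/60/250/23 by labour-force
  status). Amounts are gamma-distributed with CV 0.2. The nilf-carer
  calibration is 320 + 23 = AU$343/week mean total welfare.
* **Tax.** A synthetic piecewise-linear progressive schedule on annualised
  earned income (0% to 20 000, 20% to 60 000, 34% to 180 000, 45% above),
  divided back to weekly. It reproduces "tax rises with income" and the
  zero-income → zero-tax convention without encoding any statutory scale.
* **Benchmarks.** Cell targets grow at a compound annual rate; the default
  0.011/year is chosen so the carer population grows 53 700 → ≈63 300
  over 2015–2030 (+18%), the growth a demographically driven carer
  projection implies. Carer cells grow with the same rate as the
  demographic cells — carers keep the same propensity to care.
* **Waves.** The generator emulates the pooled multi-wave base file as a
  single file with a provenance column (`wave`) that nothing downstream
  uses: once the pooled file is reweighted to common benchmarks,
  wave-specific weights are moot. Pooling (rather than wave
  stratification) is this package's choice.

What the generator does **not** emulate: item non-response and imputation
flags, household clustering and design effects, correlation between
education and age or between caring intensity and hours worked, and any
real tax/transfer schedule. Passing tests therefore demonstrate that the
*pipeline machinery* is correct under known conditions — not that the
synthetic numbers describe any real carer population.

## Reweighting (GREGWT-style calibration)

`gregwt_solve()` implements linear GREG calibration under the chi-square
distance: minimise $\sum_i (w_i-d_i)^2/d_i$ subject to $X'w = T$, solved
in closed form via $(X'DX)\lambda = T - X'd$, $w = d(1+X\lambda)$. The
chi-square distance is chosen because its inner solve is exact and
checkable against a generic equality-constrained quadratic-programming
oracle (the suite solves the full KKT system independently and requires
elementwise agreement to 1e-8 on random instances).

Numerical choices:

* Convergence is measured as the maximum relative gap with denominator
  $\max(1, T_j)$, which stays defined for zero-target cells. Tolerance
  1e-6, default 100 clamp iterations.
* Bounds, when given, are per-record $[l_i, u_i]$ with $l_i \le d_i \le
  u_i$; violating weights are clamped, removed from the free set, and the
  residual system re-solved. If clamping strips a constraint of all free
  members the residual system is singular and the run returns
  `converged = FALSE` with diagnostics rather than erroring.
* Negative weights — possible under unbounded GREG with overlapping
  constraint families — are meaningless as person counts, so by default a
  run that produces any is transparently redone with a lower bound of
  zero; `allow_negative = TRUE` restores raw GREG behaviour.
* A collinear constraint set (e.g. two exhaustive families plus a grand
  total) fails fast with advice to drop a redundant family.
* Records matching no benchmark cell keep their design weights; the
  closed form does this automatically (their rows of $X$ are zero) and
  they are flagged.

The benchmark variable list is configuration, not doctrine: the default
families are age-band × sex plus carer-status × cared-condition, which
calibrates both demography and carer numbers.

## Statistical matching

Economic attributes are fused onto the person file by cell-exact hot-deck
matching on (age band, sex, education, labour-force status, carer status):
all matching variables are categorical, which keeps the behaviour fully
auditable — every imputed record names its donor and the coarsening level
used. When a recipient's exact cell has no donor, variables are dropped
cumulatively in the order education → labour-force status → age band (sex
and carer status are always retained). Dropping, rather than partially
collapsing, a variable is this package's simplification: it needs no
auxiliary category maps, and with the shipped donor generator (which
guarantees every population cell at least one donor) the fallback only
engages on user-supplied donor files. Donor draws are
weight-proportional by default, so large-weight donors are reproduced at
their population frequency; the suite checks that imputed cell means
converge to donor-pool weighted cell means.

## Counterfactual estimation

`run_monte_carlo()` implements the matched Monte Carlo estimator. Per
iteration $k$ and carer $i$, one pool member $j(i,k)$ is drawn with
replacement from the carer's (age band, sex, education) cell; the same
drawn record supplies all outcomes, preserving their within-person
coherence. The iteration statistic is the carer-weight-weighted mean
$\bar\delta_k = \sum_i w_i\,\delta_{ik} / \sum_i w_i$; the point estimate
averages the 5000 $\bar\delta_k$ and the 95% CI takes their 2.5th and
97.5th empirical percentiles (linear interpolation between order
statistics, the standard type-7 convention).

Sign convention: all differences are stored counterfactual − carer. The
report layer flips welfare to carer − counterfactual, so income and tax
read as losses and welfare as extra payments — all three positive in the
expected direction.

Design choices made here:

* Weight-proportional donor draws by default (pool members represent
  unequal population counts); uniform draws are available for sensitivity
  analysis. Iteration means are carer-weight weighted because the
  estimate describes the represented population, not the sample.
* Matching-cell fallback (widen the age band to 10 years, then drop
  education) exists but is **off** by default: an empty cell errors with
  its name, so coarsening is always an explicit analyst decision.
* The full-time and part-time comparisons use pools restricted to exactly
  that employment status (unemployed excluded); the broad pool includes
  the unemployed with their recorded incomes unadjusted.
* Weekly CIs and annual aggregate CIs are computed from the same
  iteration draws; because annualisation is linear they are
  order-consistent, and the suite asserts the exact proportionality.

The suite validates the estimator against exact enumeration (one carer,
two donors), against constructed populations with a known cell-wise gap of
AU$500, and for CI behaviour: each coverage replicate redraws carers and
pool from a superpopulation with true gap 500 and checks that the
percentile CI covers that construction truth. The replicate design
(20 carers, 200 pool members, equal spreads) is sized so the interval
width — driven by single-draw matching noise — is commensurate with the
estimator's sampling error, placing nominal coverage near 94%; a CI
checked against the *conditional* (given-data) expectation would cover
essentially always and test nothing.

## Aggregation and reporting

Annualisation multiplies weekly values by `weeks_per_year`, default 52.0
(365.25/7 ≈ 52.18 is available via the argument); the constant is a
reporting convention, not an estimate. National aggregates are
$A_k = \sum_i w_i \delta_{ik} \times 52$ per iteration, in AU$ million;
stratified aggregation reuses the same draw matrices, so per-stratum
aggregates sum to the national ones to floating-point accuracy — a
conservation law the suite enforces rather than a statistical claim.
Report tables keep full precision in machine-readable columns and round
only the `printed` columns (AU$1 for weekly values, AU$0.1 million for
aggregates, whole percent for change rows).

## Problem sizes

Default study conditions are 50 000 survey records, 20 000 donors and
5000 Monte Carlo iterations — the sizes `scripts/acceptance.R` runs. The
test suite uses smaller instances chosen for statistical adequacy of each
check (e.g. 2000–6000 records for pipeline properties, 500 iterations and
200 replicates for coverage, 30 random instances for the QP oracle); these
are the package's own test designs and complete in seconds.

## Known limitations

* No behavioural responses: labour-supply, benefit take-up and wage
  distributions do not react to projected incomes.
* Indexation is distribution-neutral (one rate per variable), so income
  inequality within groups is frozen at its base-year shape.
* The estimator is exact-cell matching only; no propensity scores or
  regression adjustment, and only the main reason for being out of the
  labour force is modelled (no secondary reasons, no underemployment).
* Economics are imputed once in the base year and indexed, not re-imputed
  per projection year; with flat growth rates the two are equivalent up to
  the common growth factor.
* Percentile CIs inherit the method's known small-sample asymmetry; with
  very few carer records the intervals are wide and discrete.
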