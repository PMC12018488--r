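---
title: "Pragmatic subgroup discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pragmatic subgroup discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pragsub)
```

This vignette is the package's own account of its statistical content: the
two-step model, its assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical choices a maintainer would want written down.
It states no empirical result that the test suite or `scripts/acceptance.R`
do not themselves compute.

## The estimand and the two-step split

For a two-arm randomized trial with binary treatment $A$, covariates $X$ and
a binary outcome reverse-coded so $Y = 1$ means event-free at the horizon,
the estimand of Step 1 is the conditional average treatment effect on the
risk-difference scale,

$$\tau(x) = E[Y^{A=1} - Y^{A=0} \mid X = x] = \mu_1(x) - \mu_0(x),$$

with $\mu_a(x) = P(Y = 1 \mid A = a, X = x)$. Reverse coding makes larger
$\tau$ mean larger benefit, so rankings, trees and group tables all read
"group 1 = lowest benefit" consistently.

The workflow's premise is that the covariates that make $\hat\tau$ accurate
(Step 1, any format, any model) and the covariates a decision-maker can act
on (Step 2, categorized at familiar clinical cutpoints, non-actionable ones
removed) are different sets, and that conflating them damages either
predictive accuracy or relevance. Step 1 therefore fits on everything;
Step 2 re-describes the fitted $\hat\tau$ surface in a restricted,
interpretable vocabulary and then *validates* the resulting groups with an
estimator whose unbiasedness does not depend on the Step 1 model.

## Step 1: estimation

### Censoring weights

Subjects lost to follow-up before the horizon have undefined outcomes.
`fit_censoring_weights()` fits a main-effects logistic regression of the
retention indicator on treatment and all covariates — all subjects enter the
fit — and weights each retained subject by the inverse fitted retention
probability. The identifying assumption is missing-at-random: retention may
depend on treatment and covariates but not on the (unobserved) outcome,
which is exactly how the synthetic generator censors.

* `truncation_quantile = 0.99`: weights are capped at the 99th percentile of
  the retained-subject weight distribution. A standard positivity safeguard;
  at the default ~6% censoring the cap rarely binds (a handful of subjects
  in a 4,000-subject trial).
* Degenerate retention (everyone retained) short-circuits to unit weights;
  a non-converged or separated fit falls back to the intercept-only model
  (weights $n/n_{\text{retained}}$), recorded in the metadata rather than
  failing the pipeline.

### The reference CATE estimator

`fit_cate_model()` is an honest T-learner: for each arm separately, an
ensemble of `n_trees` weighted regression trees is fit to $Y$ among retained
subjects, and $\hat\tau = \hat\mu_1 - \hat\mu_0$. Each tree is grown on a
bootstrap draw whose first half determines the splits (maximal weighted
squared-error reduction, exhaustive threshold scan) and whose second half
supplies the leaf means. This *honesty* decouples where the tree cuts from
what it predicts, which shrinks the overfitting component of
$\mathrm{Var}(\hat\tau)$; the test suite checks, over replicate null
datasets, that the honest ensemble's $\hat\tau$ variance does not exceed the
adaptive (non-honest) one's.

Defaults and rationale:

* `n_trees = 200` per arm — the $\hat\mu_a$ curves stabilise well before
  this at $n \approx 4{,}600$; fitting both arms takes ~20 s on one CPU.
* `min_leaf = 20` on the split sample — keeps leaf means (estimated from the
  other half) from collapsing onto single subjects; no depth cap, since
  honesty plus the leaf floor already bound the variance.
* 50/50 honesty split of each bootstrap draw; an empty estimation leaf
  inherits its parent's estimation mean.
* Categorical covariates are one-hot encoded; the factor levels seen at fit
  time are frozen into the model schema, and prediction refuses unseen
  levels or missing/extra columns (a contract error, not a silent guess).
* All bootstrap indices are drawn in R from one `seed` argument and passed
  to the compiled backend, so a fit is reproducible from a single integer
  and no global RNG state is touched.

The estimator is deliberately pluggable: the model is fit on *all* retained
subjects (no sample splitting), matching the workflow it implements, so
in-sample calibration metrics carry an optimism caveat — they answer "did
the model capture structure in these data", not "will it generalize".
Externally produced per-subject estimates enter through
`read_cate_estimates()` (CSV of `subject_id, tau_hat, mu0_hat, mu1_hat`)
with provenance `"imported"` and flow through Step 2 identically; this is
the hook for posterior-mean effects from a Bayesian causal forest fit in
another environment.

### Calibration diagnostics

**Qini.** Subjects are sorted by $\hat\tau$ descending (ties broken by
subject id, making the curve a deterministic function of the estimate); at a
prefix of the first $k$ subjects,

$$\text{uplift}(k) = \sum_{i \le k, A_i = 1} w_i Y_i \;-\;
  \Big(\sum_{i \le k, A_i = 0} w_i Y_i\Big)\frac{W_1(k)}{W_0(k)},$$

with $W_a(k)$ the IPCW weight totals per arm in the prefix; prefixes with
$W_0(k) = 0$ are omitted. The coefficient is the trapezoidal area between
this curve and the straight line to the total uplift (the expected curve
under random ordering). A positive coefficient means the ranking
concentrates benefit better than chance.

Two numerical facts about this estimator, found while verifying the
implementation and worth knowing:

* The $W_1/W_0$ correction is a ratio estimator. Conditional on one fixed
  dataset, the *permutation* distribution of the coefficient has a small
  dataset-dependent bias (on the order of one outcome count, either sign,
  not removable by trimming small prefixes). Across freshly drawn null
  datasets the coefficient is centered at zero — that is the form in which
  the null-behavior property is tested.
* Negating all $\hat\tau$ flips the coefficient's sign exactly only when
  every evaluated prefix is arm-balanced (e.g. interleaved arms on an
  even-prefix grid, equal per-arm outcome totals); in general the ratio
  correction breaks exact antisymmetry. The test constructs the balanced
  case, where the identity is provable.

The y-scale is configurable: `"counts"` (default; coefficient in weighted
outcome counts × sample fraction, which grows with $n$) or `"per-subject"`
(divided by the total weight; scale-free). The sort direction is
descending-benefit, which preserves the convention that a positive
coefficient indicates better-than-chance calibration.

**C-for-benefit.** Treated and control subjects are each ranked by
$\hat\tau$ and matched by rank; the surplus lowest-ranked subjects of the
larger arm are dropped. A pair's observed benefit is
$Y_{\text{treated}} - Y_{\text{control}} \in \{-1, 0, 1\}$ and its predicted
benefit the mean of the two $\hat\tau$ values. The statistic is the
probability, over pairs of pairs with unequal observed benefit, that the
pair with larger observed benefit also has strictly larger predicted
benefit, ties counted ½ — a concordance index for treatment benefit; 0.5 is
chance. Because both matched sequences are sorted, any strictly increasing
transform of $\hat\tau$ preserves all pairwise comparisons, so the statistic
depends only on the ranking (tested). The confidence interval is a
percentile bootstrap (default `n_boot = 200`, level 0.95) resampling
subjects *within arm* and re-pairing each replicate, seeded. If no two pairs
differ in observed benefit the statistic is undefined and flagged
degenerate rather than invented.

## Step 2: discovery and validation

### Interpretable recoding

`apply_recoding()` executes a declarative ruleset: per raw covariate one of
`keep`, `categorize` (strictly increasing cutpoints + ordered labels) or
`remove`. Intervals are half-open $[c_k, c_{k+1})$ with open ends
$(-\infty, c_1)$ and $[c_K, \infty)$: printed clinical ranges like
"6.4–6.9" reflect one-decimal rounding, and the half-open convention turns
them into an exact partition of the reals (tested on a dense grid:
exhaustive, mutually exclusive, monotone in the raw value). So HbA1c 6.95
falls in "6.4–6.9" and exactly 7.0 starts "7.0–7.9"; age 60.0 is "≥ 60".

The shipped default ruleset (`inst/extdata/table2_lookahead.yaml`,
`default_rules()`) encodes familiar clinical groupings — age at 60, BMI at
18.5/25/30/35/40, HbA1c at 5.7/6.4/7/8/9/10, SBP in six groups, SF-36
scales dichotomized at the population-normed 50, Beck depression in four
bands — and removes five non-actionable lab/summary variables, turning the
47-covariate roster into 42 interpretable covariates. Two transcription
oddities are preserved deliberately and documented in the file: the fasting
glucose bands (< 54 / 54–69.9 / ≥ 70) are clinically unusual for a diabetes
population but kept verbatim, and the Beck bands overlap at 10 in print;
the integer-valued score resolves this with a cutpoint at 11 (10 falls in
the first band). Cutpoints live in configuration, not code, because
different audiences warrant different codings; `validate_rules()` reports
rules referencing absent variables and categories no subject occupies,
without mutating anything. Missing values propagate as missing — imputation
(median/mode via `impute_simple()`, a deliberate simplification of
model-based imputation, pluggable upstream) happens before recoding in the
pipeline.

### The subgroup tree

`fit_tree()` is CART with squared-error impurity on the estimated
$\hat\tau$, written from first principles so its behavior is fully
deterministic and checkable against brute force:

* Ordinal covariates (numeric, ordered factors — including every recoded
  clinical category) split only on order-respecting thresholds, so rules
  read "HbA1c ≥ 7.0–7.9" rather than arbitrary level subsets — the payoff
  of Step 2.
* Unordered factors with ≤ 8 observed levels are split by *exhaustive*
  subset enumeration. The classical shortcut — order levels by mean response
  and scan prefixes — is exact only without size constraints; under a
  `min_leaf` floor the constrained optimum can be non-contiguous in the mean
  order (observed in randomized checks), so exactness is bought by
  enumeration where it is cheap and the mean-order scan retained as the
  fallback above 8 levels.
* Tie-breaking is total and documented: larger SSE reduction, then variable
  name (lexicographic), then lower threshold / first subset in canonical
  order. Permuting subject order cannot change the fitted tree (tested).
* Stopping: `max_depth` (default 2 — subgroups described by at most two
  conditions), `min_leaf` (default 50 — a subgroup smaller than this is not
  a reportable clinical stratum), or zero achievable reduction. No
  cost-complexity pruning: the depth cap *is* the complexity control in
  this workflow.
* Leaves are labelled group $1..G$ by ascending mean $\hat\tau$, so group 1
  is always "lowest benefit". `assign_groups()` replays routing exactly;
  unseen categorical levels at assignment time are routed to the complement
  side of the subset rule and reported, not errored, since scoring new data
  must not fail on a rare level.

The depth-1 greedy fit is verified to coincide exactly with an independent
exhaustive search over all admissible single splits on 1,000 random small
instances, and on the planted 4-cell scenario with oracle effects the
depth-2 tree recovers the true partition in ≥ 95% of replicates (both are
acceptance criteria).

### AIPW validation

`aipw_scores()` computes per-subject influence values

$$\psi_i = \hat\mu_1(x_i) - \hat\mu_0(x_i)
  + \frac{A_i\,(Y_i - \hat\mu_1(x_i))}{e}
  - \frac{(1-A_i)\,(Y_i - \hat\mu_0(x_i))}{1-e}$$

once, globally; `group_ate_table()` aggregates them per discovered subgroup
with the IPCW weights (weighted mean in percentage points, SE from the
weighted variance over the Kish effective sample size, normal ±1.96 SE
intervals — the interval method is a package choice). Computing $\psi$ once
and aggregating is arithmetically identical to per-group estimation with
shared nuisance fits, and makes the decomposition "overall = weight-total
weighted average of groups" exact (tested as an identity).

The propensity defaults to the *known* randomization share rather than an
estimated one: in a randomized trial, known-$e$ AIPW is unbiased for each
group's ATE regardless of how wrong $\hat\mu_a$ is (double robustness with
one lever guaranteed). The test suite verifies unbiasedness within Monte
Carlo error and ~95% CI coverage under a deliberately misspecified constant
outcome model. When the estimate carries no arm predictions (e.g. the
oracle), zeros are substituted and $\psi$ degrades gracefully to the IPW
difference-in-means contribution — unbiased still, with larger variance. No
multiplicity adjustment is applied across groups; the table is a validation
display, not a testing procedure.

## The synthetic generator: what it emulates, and what a green test proves

`simulate_trial()` emulates the *shape* of a large lifestyle-intervention
diabetes trial: 4,600 subjects by default, 47 covariates (30 continuous, 12
binary, 5 categorical) whose names and rough marginals mirror that setting
(labs, blood pressure, SF-36 scales, depression score, histories,
demographics), 1:1 randomization, a binary 7-year outcome reverse-coded with
a 13% event rate, and ~6.2% loss to follow-up from a logistic model on
treatment and covariates (MAR by construction — never on the outcome).

Design choices worth stating:

* **Outcomes are generated directly on the probability scale**:
  $P(Y=1) = (1 - \text{baseline risk}) + \text{prognostic shift}(x) + A\,\tau(x)$,
  so the planted cell effects are *exact* risk differences and oracle checks
  are closed-form. The prognostic shift (age and HbA1c acting through a
  bounded logistic transform, amplitude ±0.04 at default strength) makes
  outcome and censoring share covariates — the regime IPCW exists for —
  while keeping all probabilities provably inside [0, 1]; configurations
  that would escape the unit interval are rejected naming the offending
  cell.
* **The planted scenarios**: `null` ($\tau \equiv 0$), `step_subgroups`
  (a 2×2 grid over the binary history covariates with default effects
  +0.08/+0.03/0.00/−0.10 — a 0.18 span, chosen so the extreme cells are
  clinically meaningful against a 13% event rate), and
  `continuous_threshold` (effect switching at HbA1c 7). The scenario
  covariate prevalences (0.30 and 0.25, independent) are deliberately higher
  than such histories' real-world prevalences so every planted cell holds
  ≥ ~7% of subjects and depth-2 recovery at `min_leaf = 50` is well-posed;
  set once, not tuned.
* **One seed, one generator**: every draw flows from the config's single
  integer seed through a private RNG scope; the caller's `.Random.seed` is
  never modified. Identical configs produce byte-identical datasets.

What the generator does *not* emulate: the joint correlation structure of
real trial covariates (marginals only), time-to-event outcomes (the horizon
is dichotomized by design), informative (MNAR) censoring, and missing
covariate values (tests inject those explicitly). A green test therefore
establishes the *procedures* — estimation tracks planted heterogeneity,
calibration metrics separate signal from null, CART recovers planted
partitions, AIPW/IPCW are unbiased where theory says they should be — on
favorable, correctly specified data. It does not establish that any given
real-data fit is well calibrated; that is precisely what the Step 1
diagnostics must show per dataset.

## Reproducibility and orchestration

`run_pipeline()` derives each stochastic stage's seed deterministically from
the master seed (FNV-1a hash of `seed:stage`, kept below $2^{31}$), writes
every intermediate artifact, and embeds a config hash (timestamps excluded)
in `report.json`; two runs with the same config and seed produce identical
artifacts. Non-retained subjects appear in the censoring fit and nowhere
downstream; every reported table shares the same analytic n. Test
replicate counts in module tests are scaled down where the acceptance suite
runs the full counts (noted in comments); no test is gated on environment
variables.

## Known limitations

* In-sample calibration (the no-splitting workflow) is optimistic; the
  C-for-benefit on training data should be read as an upper bound.
* A single CART on point estimates of $\hat\tau$ can displace a weak true
  split with a correlated noise covariate (visible in the README example);
  the AIPW table is the guardrail, and ensemble-of-trees subgroup methods
  are out of scope here.
* Percentile bootstrap intervals for C-for-benefit are approximate; the
  coverage test is deliberately loose (≥ ~80–90%).
* The Qini coefficient in `"counts"` scale grows with $n$; compare runs on
  the `"per-subject"` scale.
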