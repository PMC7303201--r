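---
title: "Designing multi-omic experiments: power, sample size and learning curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multi-omic experiments: power, sample size and learning curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multipower)
```

## The design problem

A multi-omic study measures the same biological contrast on several
platforms at once — say RNA-seq, proteomics and metabolomics on the same
two groups of samples. Each platform has its own number of features $m_i$,
its own noise level, its own expected fraction of truly changed features
$p_{1,i}$, and its own cost per replicate $c_i$. Sizing such an experiment
platform by platform ignores that the data will be analyzed jointly: a
design that gives RNA-seq power 0.99 and proteomics power 0.3 will not
support integrative analysis.

`multipower` treats the design as one constrained optimization: choose the
per-group sample sizes $x_1, \dots, x_I$ to

$$\min \sum_{i=1}^{I} 2\,c_i x_i
\quad\text{s.t.}\quad
f_i(x_i, \alpha^*_i) \ge P_i \;\;\forall i,
\qquad
\frac{1}{I}\sum_i f_i(x_i, \alpha^*_i) \ge A,$$

where $f_i$ is the power function of the test appropriate to omic $i$'s
data type, $P_i$ is the minimum acceptable power per omic and $A$ is the
minimum average power across the experiment. The factor 2 reflects the two
experimental groups.

## Power functions per data type

Three data types are supported, each mapped to the test a practitioner
would use feature-wise:

* **normal** — two-sided, equal-variance two-sample $t$ test. Power
  depends on the absolute mean difference $\Delta$ and the pooled standard
  deviation (PSD) $\sigma$; it is computed from the noncentral $t$
  distribution with $\mathrm{ncp} = (\Delta/\sigma)\sqrt{n/2}$ via
  `stats::power.t.test()`. Both rejection tails are counted, so the power
  at $\Delta = 0$ equals $\alpha$ exactly.
* **count** — the two-group conditional exact test for negative-binomial
  counts, with dispersion $\phi$ tied to the mean by
  $\sigma^2 = \mu + \mu^2\phi$, fold change $\omega$, and a
  sequencing-depth ratio $w = D_B/D_A$. `power_count()` enumerates the
  joint distribution of the two group sums, builds the two-sided
  rejection region from the conditional law of $S_A$ given the total
  (evaluated at the conditional MLE of the common mean), and accumulates
  the rejection probability under the alternative. For equal depths its
  p-values coincide with `edgeR::exactTest()`, which the test suite uses
  as an independent simulation oracle (agreement within 0.02 on a
  $3 \times 3$ grid at 10,000 replicates). Because the enumeration costs
  $O(T^2)$ in the expected total count $T = n\mu(1 + w\omega)$, totals
  above 5,000 switch to an asymptotic normal test on the log fold change
  with variance $1/(n\mu) + \phi/n + 1/(n w \omega \mu) + \phi/n$; at the
  crossover the two agree to well under 0.01.
* **binary** — two-sided two-sample test of proportions
  (`stats::power.prop.test()`, strict), parameterized by the two group
  proportions $(p_A, p_B)$.

Tests are two-sided throughout, matching the defaults of the underlying R
functions; one-sided designs and Welch corrections are out of scope.
Power is only ever evaluated at integer $n \ge 2$.

## Multiple testing: the adjusted significance level

Testing $m$ features at FDR $\alpha$ is incorporated at design time by
adjusting the per-test level to

$$\alpha^* = \frac{r_1\,\alpha}{(m - m_1)(1 - \alpha)},$$

with $m_1 = m\,p_1$ expected changed features (kept unrounded) and $r_1$
expected true detections. `adjust_alpha()` assumes $r_1 = m_1$ for all
data types — for count data this is a conservative simplification (the
count-data literature estimates $r_1 < m_1$ iteratively) and can be
overridden via the `r1` argument. With $r_1 = m_1$ the adjustment depends
only on $p_1$ and $\alpha$, so omics with equal DE fractions share
$\alpha^*$ regardless of $m$:

```{r}
adjust_alpha(m = 1077, p1 = 0.2, alpha_fdr = 0.05)
```

## Estimating power parameters from pilot data

Given a pilot matrix with two groups and at least two replicates per
group, `estimate_power_params()` runs:

1. **Depth normalization (counts only).** Each sample is divided by its
   column-sum depth relative to the median depth; the depth ratio
   $w = D_B/D_A$ is the ratio of group geometric-mean depths.
2. **Per-feature statistics.** Group means, mean difference, per-group
   variances, PSD, and a standardized effect size $d$: Cohen's
   $d = |\Delta|/\mathrm{PSD}$ for normal data, Cohen's $d$ of
   $\log_2(x + 1)$-transformed normalized counts for count data (the
   transform makes the selection threshold scale-free and comparable
   across omics; it is isolated in `compute_feature_stats()` and used for
   selection only), and Cohen's $h = |2\arcsin\sqrt{p_A} -
   2\arcsin\sqrt{p_B}|$ for binary data.
3. **Pseudo-DE selection.** Features with $d$ strictly above the initial
   threshold $d_0$ (default 0.8, a conventionally "large" effect) form the
   estimation population. An empty set raises an error advising a lower
   $d_0$.
4. **Percentile summaries.** One parameter bundle per omic must summarize
   a whole distribution of per-feature parameters. The dispersion is the
   $P_k$ percentile of the pseudo-DE PSDs (default $k = 75$ — a
   deliberately conservative choice); the effect size is the $P_{100-k}$
   of the absolute mean differences among pseudo-DE features whose PSD
   falls in the $[P_{k-5}, P_{k+5}]$ window, which avoids anchoring the
   design to a single feature. For counts, the per-condition variance
   $P_k$ yields $\phi = (\sigma^2 - \mu)/\mu^2$ (floored at 0), $\mu$ is
   the $P_{100-k}$ of reference-group means inside the variance window,
   and $\omega$ is the $P_{100-k}$ of direction-folded fold changes
   ($\max(\mathrm{fc}, 1/\mathrm{fc})$, so up- and down-regulation are
   treated symmetrically; features with zero reference mean are excluded)
   inside the PSD window. For binary data the $(p_A, p_B)$ pair of the
   feature closest to the $P_{100-k}$ of the $h$ distribution is returned.

Numerical choices worth knowing: quantiles are linear-interpolation
type 7 (the R default; percentile-based outputs shift by a feature or two
under other quantile types); an empty percentile window is widened symmetrically in
5-percentile steps with a warning; low-count filtering is left to the
caller (`filter_low_counts()` is provided but off by default, removing
features with mean count below 1 when used).

Two consequences of the percentile scheme should temper expectations on
real data. First, it is *conservative by construction*: the dispersion is
taken from the pessimistic end while the effect comes from the
conservative end, so the implied design-level Cohen's d is smaller than
the typical per-feature truth, and the recommended $n$ errs high. Second,
for count data the variance percentile stacks both conditions, and a
feature changed by fold $\omega$ has one condition at roughly
$\omega^2$-fold higher NB variance — so $\phi$ estimates inflate with the
effect size. The validation suite therefore checks unbiased recovery only
where it is mathematically expected (per-feature Cohen's d on normal
pilots, median within $\pm 0.1$ of truth; the Poisson limit for counts)
and otherwise pins the conservative envelope.

## Solving for the optimal design

**Equal sizes** (`solve_equal()`): the minimum $n$ per omic is found by
bisection on the monotone power curve; the shared size starts at the
maximum of these minima and grows until the average-power constraint
holds. Costs cannot change this solution.

**Unequal sizes** (`solve_unequal()`): the nonlinear integer program is
the classical 0–1 linearization over indicator variables $z^i_n$ ("omic
$i$ uses size $n$"). Rather than depending on an external MILP solver,
the package ships an exact branch-and-bound: per-omic candidate lists run
from the per-omic minimum to $n^i_{\max}$, candidates that add cost
without adding power are dropped, a greedy power-per-cost incumbent
provides the initial bound, and suffix bounds on remaining cost and
attainable power prune the search. Optimality is certified in the test
suite against exhaustive enumeration on randomized instances
($I \le 4$, $n_{\max} \le 15$, 50 instances). Ties are broken toward the
smaller total sample size, then lexicographically. Average power is the
unweighted mean over omics.

```{r}
opps <- list(
  manual_power_params("Proteomics", normal_params(1.16, 1.05),
                      m = 1077, p1 = 0.2),
  manual_power_params("Metabolomics", normal_params(1.20, 0.52),
                      m = 60, p1 = 0.6))
solve_equal(opps, design_constraints(min_power = 0.6, avg_power = 0.8))
```

## Power-study diagnostics

After the design is solved, three diagnostics support the budget
conversation:

* `power_vs_n()` tabulates power against sample size (default 2–35, the
  range where designs typically live);
* `power_vs_dispersion()` repeats the curves at other dispersion
  percentiles (strictly between 5 and 95), showing how much the
  conservative $k = 75$ costs;
* `post_d_grid()` re-estimates all parameters on a grid of 40 Cohen's d
  thresholds from $d_0$ to $d_{\max}$ and re-solves the design at each,
  answering "what effect size could we still detect with only $n$
  replicates?". $d_{\max}$ is the smallest per-omic 90th percentile of
  feature effect sizes, which guarantees at least 10% of features remain
  for estimation; the $\alpha^*$ values do not change along the grid
  because they depend only on $(m, p_1)$. For an `n_target`, the smallest
  grid d whose optimum fits the budget is reported (a conservative
  readout). Monotonicity of the grid holds up to re-estimation noise;
  plots are data tables first (`plot_power_curves()` renders them).

Designs with three or more groups reduce to all (or selected) pairwise
comparisons (`multigroup_design()`); the global size is the maximum over
comparisons, so every contrast is adequately powered, at the price of not
allowing group-specific sizes.

Without pilot data, `defaults_without_pilot()` encodes field-informed
starting points: $\sigma = 1$ for normalized continuous omics, fold
change 2 at mean count 30 for sequencing counts — with a dispersion of
0.5, a deliberately conservative bulk-tissue-scale value since no
published default exists — and proportions placed a Cohen's h of $d_0$
apart for binary data. All of these require review against the platform
at hand.

## Learning curves for multi-omic classifiers

When the goal is classification (e.g. tumor subtype from several omics)
rather than feature-wise testing, significance levels and effect sizes no
longer parameterize the problem; the relevant question is how the
classification error rate (ER) falls as samples accrue. `multiml()`
estimates that learning curve from pilot data and extrapolates it:

1. Align the chosen omics on their common observations ($N_{\max}$).
2. Choose subset sizes ("ticks") from two observations per class up to
   $N_{\max}$, starting with 5 ticks.
3. At each tick, repeat $m$ times (default 15): draw a stratified subset,
   select variables by LASSO (`glmnet`, penalty by internal
   cross-validation, itself repeated over subsamples — variables kept
   when selected in at least half the repeats, falling back to the union,
   and, on signal-free data, to the first variables entering the
   regularization path so evaluation can still report chance-level
   error); then draw a fresh subset of the same size and measure the ER
   of the chosen learner — random forest (500 trees; out-of-bag error,
   or stratified ten-fold / leave-one-out CV) or PLS-DA.
4. Fit a first-order penalized P-spline through the tick means with
   effective degrees of freedom equal to ticks − 1, add one tick at a
   time, and stop when three consecutive fits agree within 0.005 absolute
   ER on at least 12% of a common grid (an operationalized form of the
   stop rule; the predicate lives in one function and is swappable), or
   when the tick budget is exhausted.
5. Invert the curve at the target ER: the predicted sample size (PSS) is
   the smallest $n$ whose predicted ER is at or below the target,
   searching up to ten times $N_{\max}$ with linear extrapolation beyond
   the last tick; past the cap the target is reported unreachable. The
   margin of error (MOE) is the distance in samples to where the
   upper-95%-CI spline (same smoothing parameter) crosses the target.
   When no target is given, the ER observed at the full pilot size is
   used.

For PLS-DA the omic blocks are kept separate: one PLS-DA per block, with
class prediction from the weight/loading/coefficient matrices as
$\hat{Y} = X_{\mathrm{new}} W (D^{\mathsf T} W)^{-1} B$ and predicted
scores $T_{\mathrm{pred}} = X_{\mathrm{new}} W (D^{\mathsf T} W)^{-1}$,
averaged across blocks before the distance rule (maximum, centroid —
the default — or Mahalanobis on the predicted scores) assigns a class.
The block-combination rule (averaging) is the package's choice; the
per-block predictions themselves are verified against direct matrix
algebra to $10^{-10}$ in the tests. The number of components defaults to
$H = 3$ (capped by rank) and is configurable; how to choose $H$ per tick
is genuinely open, and the default favors stability at small ticks.
Tick sizes are totals with a floor of two per class (the per-class
versus total ambiguity is resolved toward totals). Random forests
constrain the selected variables of all omics into one wide matrix, as
is standard.

Everything is driven by one mandatory seed: per-(tick, iteration) seeds
are derived deterministically, so runs are bit-reproducible, tick results
are cached and reused as ticks are added, and `multiml_jobs()` exposes
the same partitioning for users who want to farm iterations out to a
scheduler. Runtime scales roughly with ticks × iterations × LASSO
repeats; the examples here and the test suite use reduced settings
(`m = 3`–`4`, `sel_reps = 3`–`4`, `ntree = 100`–`150`, tick caps of
7–9 on datasets of 40–50 observations) so the whole suite runs in
minutes; production runs on real cohorts should keep the defaults.

```{r, eval = FALSE}
d <- gen_ml_dataset(n_per_class = 25, omics = 2, separation = 1.5, seed = 1)
run <- multiml(d, ml = "rf", cv = "oob", er_target = 0.1, seed = 7)
plot_learning_curve(run)
```

## What the synthetic data do and do not emulate

The generators exist so every stage is testable with known ground truth:

* `gen_normal_omic()` plants a fraction $p_1$ of features with a mean
  shift $\Delta$ (random sign) on $N(0, \sigma^2)$ noise; null features
  give uniform t-test p-values.
* `gen_count_omic()` draws NB counts honoring
  $\sigma^2 = \mu + \mu^2\phi$ (Poisson at $\phi = 0$) around log-normal
  feature means, with per-sample depth factors. Changed features are
  split between up-regulation in B and an elevated baseline in A, keeping
  expected library sizes equal — the generator is composition-neutral so
  that depth normalization is not confounded by the injected signal (a
  one-sided fold pattern would shift every null feature after column-sum
  normalization, exactly as it does in real data with globally asymmetric
  regulation).
* `gen_binary_omic()` uses uniform null proportions and a fixed
  $(p_A, p_B)$ for changed features.
* `gen_ml_dataset()` builds Gaussian omic blocks in which each
  informative variable carries class means with standard deviation equal
  to the `separation` dial; blocks are complementary by default
  (independent informative directions) or exact-signal copies with
  `redundant = TRUE`.
* `gen_multiomic_pilot()` is a six-omic fixture shaped like a typical
  transcriptome/epigenome/proteome/metabolome pilot at one tenth of the
  published feature counts, so the full pipeline runs in seconds.

Not emulated: batch effects, compositional (relative-abundance)
structure, missing values, feature–feature correlation, and
heavy-tailed noise. Passing tests on these generators therefore
demonstrate correctness of the statistical machinery under its own
assumptions, not robustness to the artifacts of any particular platform —
that is what the pilot-data path is for.

## Numerical and degenerate-input choices

* Quantiles: type 7 everywhere; documented because percentile outputs
  shift slightly across types.
* Exact NB power: support truncated at mass $10^{-12}$ per tail;
  rejection uses $p \le \alpha(1 + 10^{-12})$ to absorb rounding.
* `min_sample_size()` verifies the bisection boundary by direct
  evaluation, guarding against sub-$10^{-3}$ discreteness wiggles of the
  exact test.
* P-spline: cubic B-splines on equally spaced knots, first-order
  difference penalty (null space: constants), smoothing parameter matched
  to the target effective df by root finding; extrapolation is linear
  from the boundary value and slope. With df equal to the number of
  points the fit approaches interpolation (the penalty-free limit used in
  the tests); with the default ticks − 1 a linear trend is slightly
  shrunk toward flat, which is intended smoothing, not a defect.
* Features with zero PSD get $d = 0$ (never NaN); zero-depth samples,
  missing cells, duplicate feature IDs and unknown group labels fail fast
  with messages naming the offender.
* Infeasible designs are results, not exceptions: the binding omic (or
  the unreachable average) is named, and the CLI exits with a distinct
  status (3).

## Known limitations

* Unequal group sizes *within* one omic's comparison are not supported
  (the power functions assume balanced groups), nor are one-sided tests.
* The count-data $r_1 = m_1$ default overstates expected detections
  slightly, making $\alpha^*$ (and hence the design) marginally
  conservative.
* The dispersion estimate for count pilots inflates with the fold change
  of the changed features (see above); when an independent dispersion
  estimate is available (e.g. from a DE analysis of the pilot), passing
  it via `count_params()` + `manual_power_params()` is preferable.
* Learning-curve extrapolation is only as good as the spline beyond the
  data: a curve still falling steeply at $N_{\max}$ extrapolates
  optimistically, and the 12% stop rule is an operationalization of an
  ambiguous published sentence — both are surfaced as explicit settings
  rather than hidden behavior.
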