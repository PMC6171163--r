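---
title: "Shared-control replication designs: model, calibration and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared-control replication designs: model, calibration and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repool)
```

## The problem

A two-stage case-control association study genotypes discovery cohorts
($C_0$ controls, $C_1$ cases) at all variants, carries variants with
discovery p-value $p_d < \alpha$ into a replication stage on new cohorts
($C_0'$, $C_1'$), and declares a hit when additionally the replication
p-value passes ($p_r < \beta$), the pooled meta-analysis passes
($p_m < \gamma$), and all three effects point in the same direction.
Recruiting replication controls is often the binding cost — in
degenerative-disease studies, inter-disease comparisons, or rare-trait
studies where every case is needed for discovery.

`repool` analyses designs that re-use discovery controls at the
replication stage:

* **Method A** (standard): replication compares $C_1'$ against $C_0'$.
* **Method B** (shared controls): replication compares $C_1'$ against the
  pooled control set $C_0 \cup C_0'$, p-value $p_s$.
* **Method C** (fully pooled): both stages use $C_0 \cup C_0'$; discovery
  compares $C_1$ against it ($p_c$), replication $C_1'$ against it.

Sharing controls correlates the test statistics under the null, so running
method B or C at the unadjusted $\beta$ inflates the joint false-positive
rate. The package's central computation is the recalibrated replication
thresholds $\beta^*$ (method B) and $\beta^\perp$ (method C) that restore
the standard design's joint null hit rate $P_0$, together with the
resulting power and type-1-error profiles.

## Statistical model

For each variant, write $\mu_0, \mu_1, \mu_0', \mu_1'$ for the population
minor-allele frequencies of the four cohorts and $m_i$ for the observed
allele-frequency estimates. Cohorts are modelled as independent binomial
samples at the allele level ($2n$ draws for a cohort of $n$ diploid
individuals, Hardy-Weinberg), so $\mathrm{var}(m_i) =
\mu(1-\mu)/(2n_i)$ under the null. Each of the five test statistics
$z_d, z_r, z_s, z_c, z_m$ is a score-type two-proportion statistic: the
difference between its two (possibly pooled) group frequency estimates
over the pooled null standard error. Under the global null all five are
standard normal.

### Null correlations

Because every statistic is a linear combination of the four independent
estimators $m_i$ divided by its standard error, the null correlation of
any pair is the covariance contributed by shared cohorts over the product
of standard errors; the factor $\mu(1-\mu)$ cancels, leaving a function of
the four cohort sizes alone. `shared_correlations()` evaluates these from
first principles via the coefficient representation — no per-pair formula
is transcribed. Properties that follow directly and are verified in the
test suite:

* $\rho_{dr} = 0$ (disjoint cohorts), every other pair in $[0, 1)$;
* invariance under common scaling of all four counts;
* $\Sigma_A = \mathrm{corr}(z_d, z_r, z_m)$ is singular exactly when
  $n_0/n_1 = n_0'/n_1'$ (the meta statistic is then an exact linear
  combination of the stage statistics);
* $\Sigma_C = \mathrm{corr}(z_c, z_s, z_m)$ is singular for every design:
  with case-pool weights $v_1 = n_1/(n_1+n_1')$, $v_{1'} = 1 - v_1$, the
  identity $\mathrm{SE}_m z_m = v_1 \mathrm{SE}_c z_c + v_{1'}
  \mathrm{SE}_s z_s$ holds exactly.

The derivation is cross-checked in three independent ways: a
Monte-Carlo oracle (sample correlations of statistics computed from raw
binomial counts), the closed form for $\rho_{ds}$,
$\sqrt{n_0 n_1 n_1' / ((n_0+n_0')(n_0+n_1)(n_0+n_0'+n_1'))}$, on random
designs, and the known balanced-design values
($\rho_{dm} = 1/\sqrt2$, $\rho_{cs} = 1/3$, $\rho_{sm} = \sqrt{2/3}$).

### Threshold calibration

With $z_x = -\Phi^{-1}(x/2)$, the joint null hit rate of a method is
twice the positive-orthant probability of its statistic triple exceeding
$(z_\alpha, z_{\mathrm{repl}}, z_\gamma)$ — the factor two encodes the
same-direction rule. `adjust_thresholds()` computes
$P_0$ for method A and solves the one-dimensional root problems

$$ \mathrm{rate}_B(\beta^*) = \mathrm{rate}_C(\beta^\perp) = P_0 $$

by bisection/secant on the log rate, bracketed at
$[z_\beta,\; \max(z_\beta, \tilde z) + \rho z_\alpha + 6]$ where
$\tilde z = \sqrt{1-\rho^2}\, z_\beta + \rho z_\alpha$ is the
large-$z_\alpha$ asymptote ($\rho = \rho_{ds}$ or $\rho_{cs}$). The
solution always satisfies $\beta^\perp < \beta^* < \beta$; it exceeds the
asymptote when $\gamma$ is no more stringent than $\beta$, but can fall
below it when $\gamma \ll \beta$ (the meta constraint then dominates the
calibration), which is why the bracket anchors at $z_\beta$ rather than
at the asymptote. Solver residuals are below $10^{-12}$ on the
probability scale (typically far below; the root is polished to
$\sim 10^{-13}$ in $z$).

When no meta threshold is used ($\gamma = 1$) two conventions exist. The
package default keeps the directional rule (the meta bound becomes
$z_\gamma = 0$, i.e. sign agreement is still required). The alternative
`convention = "nondirectional"` drops the direction constraint and
conserves $\Pr(p_d < \alpha, p_s < \beta^*) = \alpha\beta$, which is the
natural two-threshold identity under independence. The two genuinely
differ for correlated designs (the directional independent-case rate is
$\alpha\beta/2$); both are exposed because published descriptions of the
two-threshold case use the $\alpha\beta$ identity while the
three-threshold definition is directional. The directional form is the
default everywhere, including $\gamma = 1$.

### Effects and noncentralities

Effect sizes are specified as a log-odds ratio plus a count-weighted mean
MAF; `freqs_from_or()` solves the two constraints for $(\mu_0, \mu_1)$ to
$10^{-12}$ and replicates them to the second stage (a true association is
the same in both populations). The expected Z-scores are first-order
normal approximations of the form

$$ \zeta = \sqrt{2\,\tilde n}\; \frac{\Delta\mu}{\sqrt{\bar\mu(1-\bar\mu)}},
\qquad \tilde n = \frac{n_a n_b}{n_a + n_b}, $$

with $\Delta\mu$ the relevant (pooled) frequency contrast. A single
count-weighted $\bar\mu$ over all four cohorts is used in every
denominator: the individual definitions differ only at $O(\Delta\mu)$,
and one consistent value makes noncentrality *ratios* exact, which the
aberrance machinery relies on. The approximation is first order: against
the simulator, analytic $\zeta$ agrees with mean simulated Z to within
about 2% at odds ratio 1.3 (and to Monte-Carlo error as the effect
shrinks); tests assert `max(4 MC SE, 2%)`.

Two aberrance parameterizations are provided. `aberrance_pattern()`
offsets cohort frequencies directly. `zeta_for_scenario()` works on the
$\zeta$ scale: it computes the pattern generated by unit offsets in the
aberrant cohorts and rescales so the driving statistic takes a requested
value — because all components share the $\bar\mu$ factor, the pattern is
exact and supports limit studies ($\zeta = 20$ and beyond). Control
misascertainment uses the mixture $\mu_0' = (1-\kappa)\mu_0 +
\kappa\mu_1$: a fraction $\kappa$ of nominal replication controls drawn
from the case population. (Published descriptions of this scenario name
the affected cohort inconsistently in one place; the package follows the
defining formula and applies $\kappa$ to the replication controls.)

### Power and error profiles

The rejection probability of a method for a variant with noncentrality
vector $\zeta$ is the sum of two shifted orthant probabilities (the
positive- and negative-direction terms) of the method's triple under its
null covariance — a mean-shift approximation that ignores the
(second-order) change of variance under the alternative. Against the raw
binomial simulator it is accurate to roughly one to two percentage points
at moderate effects; the test suite asserts agreement within 0.02
absolute. This matters when comparing designs: the analytic
between-method power differences are mildly conservative relative to
simulated differences (the simulated shared-control advantage on a
controls-rich 20000-sample design is about 1.3 percentage points larger
than the analytic value).

Power-difference summaries follow two conventions because the natural
metric has no canonical normalization: `average_power_difference()`
reports the raw integral $\int (\mathrm{Power}_X - \mathrm{Power}_Y)\,
d(\log \mathrm{OR})$ over a window grown until both powers exceed
$1 - 10^{-6}$, plus the windowed mean as a percent-style figure;
`max_power_difference()` maximizes the pointwise difference (coarse grid
of 201 points, then golden-section refinement). The difference profile is
nearly even in the log-odds ratio, so the maximizer can land on either
sign of the effect.

Type-1 error profiles under aberrance verify, along the way, the analytic
limits — e.g. aberrance confined to $C_1$ drives the rates to $\beta/2$,
$\beta^*/2$, $\beta^\perp/2$ for methods A, B, C, while aberrance in the
replication cohorts drives all three to $\alpha/2$ — and the per-cohort
upper bounds (notably: method B sacrifices the bound under $C_0$
aberrance entirely, and improves on method A under $C_0'$ aberrance,
where the discovery controls exert a correcting influence on the shared
replication comparison).

## Numerics

All probabilities flow through one deterministic kernel, `mvn_tail()`,
for 2- and 3-dimensional shifted orthant probabilities:

* Full-rank $3{\times}3$: condition on the coordinate with the largest
  lower bound and integrate the conditional bivariate tail by adaptive
  quadrature (`rel.tol = 1e-11`). The bivariate tail itself is a
  vectorized fixed Gauss–Legendre quadrature (three panels, 32 nodes) of
  the conditional normal CDF. Working with conditional densities keeps
  *relative* accuracy near $10^{-10}$ even for probabilities of order
  $10^{-20}$ ($z_\alpha$ up to 8), which calibration requires; an
  absolute-accuracy integrator loses all significant digits there.
* Rank-deficient matrices (smallest eigenvalue below $10^{-8}$ of the
  largest, which also captures condition numbers beyond $10^8$):
  `reduce_singular()` returns the exact linear dependence
  $z_3 = a z_1 + b z_2$, and the integral runs over the two free
  coordinates with the third constraint as a half-plane clipped against
  the rectangle. $\Sigma_C$ always takes this path; $\Sigma_A$ does when
  stage ratios match.
* Bounds below $-12$ are clamped (mass beyond is $< 2\times10^{-33}$);
  `-Inf` bounds drop their dimension exactly.
* No Monte-Carlo is used anywhere in the analytic path, so solved
  thresholds are bit-reproducible; the simulator exists as an oracle and
  as the estimation route for covariate-adjusted statistics.

Degenerate inputs: thresholds at 1 give a zero bound (directional) or
drop the constraint (nondirectional); monomorphic simulated replicates
(pooled frequency 0 or 1 in a compared group) are excluded and counted;
frequency specifications are confined to the open interval $(0,1)$.

## The simulator: what it emulates and what it does not

`simulate_counts()` draws per-cohort minor-allele counts
$\mathrm{Bin}(2n, \mu)$ independently across cohorts and replicates —
the minimal sampling law consistent with the variance model above — and
`statistics_from_counts()` applies exactly the score-type statistics the
analytic theory describes. A single seeded RNG stream makes runs
bit-for-bit reproducible; the seed travels in the returned object.

It does **not** emulate: linkage disequilibrium between variants,
covariate or stratum adjustment, genotyping error, population structure
within a cohort, or case-control imbalance in genotyping platforms.
Passing tests therefore demonstrate internal consistency of the
analytic machinery with its own sampling model, and the magnitude of the
first-order approximation errors — not robustness of the thresholds to
real-data artefacts. For adjusted statistics from real analyses,
`empirical_correlations()` accepts a table of Z-scores at known-null
variants and estimates the correlation structure directly, which is the
supported route when the analytic formulas do not apply.

The winner's-curse mechanism is exercised directly: conditional on
discovery success, the shared-control replication estimate is biased
toward the discovery direction, an unadjusted $\beta$ inflates the joint
null rate, and the solved $\beta^*$ restores it (verified empirically at
thresholds loose enough for null hits to be observable).

## Problem sizes used by the tests

The suite favours deterministic checks; Monte-Carlo oracles use
$2\times10^5$ replicates for correlation and null-rate agreement
($5\times10^4$ for power, where the binding error is the approximation,
not Monte-Carlo noise), one frozen $10^7$-draw brute-force orthant value,
and $10\,000$-draw reconstruction checks for the degenerate reduction.
Conservation and ordering are asserted on 50 random designs with counts
in $[300, 40\,000]$. The full suite runs in under a minute on one CPU.

## Known limitations

* The mean-shift power model is first order; for publication-grade power
  numbers at strong effects, use `empirical_rates()` (the analytic and
  empirical routes bracket the truth and differ by at most a couple of
  percentage points in our checks).
* Analytic correlations assume unadjusted difference-of-proportion
  statistics; covariate-adjusted pipelines should use the empirical
  estimation route.
* Dimensions beyond the three-statistic hit rule (e.g. multi-stage
  designs) are out of scope; the kernel is deliberately limited to
  $d \le 3$.
* Thresholds $(\alpha, \beta, \gamma)$ are taken as given; the package
  does not optimize them against cost or multiplicity.
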