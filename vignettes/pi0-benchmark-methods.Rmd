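---
title: "Estimating the proportion of true null hypotheses: models, estimators, and the simulation benchmark"
author: "pi0bench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the proportion of true null hypotheses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pi0bench)
```

## The problem

In a two-condition comparative gene-expression study, each of $M$ genes is
tested for differential expression and yields a p-value. When $M$ is in the
thousands, the fraction of genes for which the null hypothesis is actually
true, $\pi_0 = M_0 / M$, becomes the central unknown of multiple-testing
error control: the expected number of false positives at a p-value cutoff
$\alpha$ is $\pi_0 \alpha M$ whatever the correlation structure among the
tests, and the proportion of false positives among all positives (PFP, the
marginal FDR) follows from $\pi_0$, $\alpha$ and the test's power. Accurate
FDR-type inference therefore reduces largely to accurate estimation of
$\pi_0$ from the vector of p-values.

This package implements five commonly used p-value–based $\pi_0$
estimators behind one interface, a simulator of correlated two-condition
expression data with known truth, exact power/PFP calculations for the
design, and a replicated benchmark that maps which estimator is most
accurate across the $(\pi_0, \rho)$ parameter space.

## The data-generating model

A gene's expression is normal with equal variance $\sigma^2$ in both
conditions. For the $M_0 = \mathrm{round}(\pi_0 M)$ null genes the two
condition means are equal (both 0); each remaining gene gets a treatment
mean drawn once from $N(d, \tau^2)$ with $d = 2$ the typical effect. Genes
sit in blocks of $k$ with the equicorrelated covariance
$\Sigma_{ij} = \sigma^2[\rho + (1-\rho)\,\mathbb{1}(i=j)]$; blocks are
mutually independent and sampled through the Cholesky factor of $\Sigma$.
A block is never mixed: if one gene in a correlated group responds to
treatment, the genes correlated with it should respond too, so blocks are
filled with nulls first, then with differentially expressed genes, the
remainder of each segment forming a smaller block. Correlation acts across
genes within an array; arrays are independent replicates.

Each gene is then tested with the pooled-variance two-sample t-test
($\mathrm{df} = n_1 + n_2 - 2$, two-sided). Because each null gene's
marginal test is exact, null p-values are marginally Uniform(0,1) at any
$\rho$ — correlation inflates the *variance* of counts of small p-values,
not their expectation. The test suite checks both facts, using
replicate-based rather than binomial standard errors for the correlated
case, since block correlation inflates the binomial variance of the
rejection fraction.

### Defaults and why

* `n1 = n2 = 8` arrays: the smallest design whose exact power at
  $\alpha = 0.01$, $d = 2$ exceeds 0.8 while the PFP at $\pi_0 = 0.8$
  stays below 0.05 (the power table computes 0.826 and 0.046). Smaller
  designs have unrealistically low power; larger ones buy little PFP.
* `k = 5` genes per block: small co-regulated groups (pathway-sized),
  large enough that within-block correlation is felt by thousands of
  genes, small enough that blocks are numerous and the study remains
  informative.
* `effect_mean = 2`, `effect_sd = 0.5`: effects concentrated around the
  typical two-standard-deviation shift, rarely near zero (which would
  blur the null/alternative distinction) and predominantly one-signed;
  the two-sided test makes the benchmark insensitive to sign.
* `sigma = 1`: effects are expressed in units of the within-condition
  standard deviation.
* Seeds: every replicated computation takes a master seed from which
  per-replicate (and, in sweeps, per-grid-point) seeds are derived
  deterministically, so results are reproducible and independent of
  evaluation order.

## The five estimators

All five consume only the p-value vector and return an estimate clipped to
$[0, 1]$ with method-specific diagnostics.

**ZG04 (median slope).** Sort the p-values; the empirical CDF point
$(p_{(i)}, i/M)$ and the corner $(1, 1)$ define a chord of slope
$s_i = (1 - i/M)/(1 - p_{(i)})$. In the upper tail, where alternative
p-values are scarce, each chord estimates $\pi_0$; the estimate is the
median slope over $t_1 \le p_{(i)} \le t_2$ with defaults
$t_1 = 0.5, t_2 = 1$ (the upper half of the range). The index $i = M$ is
excluded (slope identically 0), as is any $p_{(i)} = 1$. The median is
preferred to the mean or minimum for robustness; with thousands of order
statistics in the default range the estimator averages over far more point
estimates than the spline-based alternatives.

**ST03 ($\lambda$-tail spline).** $\hat\pi_0(\lambda) =
\#\{p > \lambda\} / (M(1 - \lambda))$ is unbiased for $\pi_0$ as
$\lambda \to 1$ but increasingly noisy; a natural cubic smoothing spline
with 3 effective degrees of freedom is fit to $\hat\pi_0(\lambda)$ over
$\lambda = 0, 0.01, \dots, 0.95$ and read off at the largest grid value.

**PM03 (beta-uniform mixture upper bound).** The p-value density is
modelled as $f(p) = w + (1 - w)\,a\,p^{a-1}$ with $0 < a \le 1$. The MLE
$(\hat w, \hat a)$ is found by multi-start quasi-Newton optimisation on
logit-transformed parameters (nine starts on a $3 \times 3$ grid);
p-values are clipped to $[10^{-10}, 1]$ because the density diverges at 0.
The estimate is the fitted density at $p = 1$, $\hat w + (1-\hat w)\hat a$,
an upper bound for $\pi_0$. The nested pure-uniform model ($w = 1$,
log-likelihood 0) is always included as a candidate, so samples
indistinguishable from uniform return exactly 1. A test verifies on every
run that the returned likelihood beats an exhaustive $50 \times 50$ grid
over the parameter box.

**PC04 (spacing-density minimum).** With the sorted sample augmented by 0
and 1, a spacing of width $d_i$ carries density ordinate $1/(M d_i)$ at
its midpoint; tied runs are merged into the next positive spacing, which
carries the combined count. The ordinates are smoothed by local *linear*
regression (span 0.3) *weighted by the interval widths*, and $\pi_0$ is
the minimum of the smoothed curve over $[0, 1]$. The weighting is the
load-bearing numerical choice: raw ordinates near 0 are enormous and
wildly noisy (a spacing of $10^{-6}$ gives an ordinate of $10^{3}$ at
$M = 1000$), and an unweighted quadratic LOESS chases that spike and
overshoots to negative densities, collapsing the minimum to 0. Width
weighting expresses that an ordinate is informative about the density over
an interval proportional to its width, and restores the estimator to the
mid-pack accuracy its description implies. On the exact uniform grid the
smoothed curve is flat at 1; on a $0.5\,U + 0.5\,\mathrm{Beta}(0.1, 1)$
mixture the estimate sits near the true floor $0.55$.

**Ch04 (shape-constrained B-spline CDF).** A cubic B-spline approximation
to the empirical CDF is fit on $[0, 1]$ through $(0,0)$ and $(1,1)$, with
interior knots placed geometrically over $[10^{-3}, 0.2]$ — where the CDF
of a p-value mixture bends sharply — plus uniform tail knots; $\pi_0$ is
the minimum of the fitted CDF's derivative. The fit is constrained to the
shape a p-value mixture CDF actually has: nondecreasing *and concave*
(nulls are uniform; alternatives pile up near 0, so the mixture density is
nonincreasing). Without concavity, the minimum-of-derivative functional is
fragile: ECDF noise between the sparse near-zero knots produces spurious
derivative dips, and on complete-null data the estimate can collapse below
0.3. Concavity pins the minimum at $p = 1$ and makes it a stable
functional. Both constraints are linear in the derivative's B-spline
coefficients (nonnegative, nonincreasing), giving a convex cone-constrained
least-squares problem with one normalisation equality; it is solved exactly
by a small Lawson–Hanson-type active-set iteration (about a dozen
variables). Smooth reparameterisations (softmax/cumulative-sum with BFGS)
were tried first and abandoned: they have spurious stationary points on
constraint faces where the derivative saturates at zero.

## Power and PFP

Exact power of the two-sided pooled-variance t-test uses the noncentral
t distribution: $\delta = d / (\sigma\sqrt{1/n_1 + 1/n_2})$,
$\mathrm{power} = P(T' > t^*) + P(T' < -t^*)$ with $T' \sim
t_{\mathrm{df}}(\delta)$ and $t^*$ the upper $\alpha/2$ quantile. The
one-sided version does not reproduce the package's tabulated design values
(at $n = 8$ it gives $\approx 0.90$, not 0.826), so the two-sided form is
the one used and tested. PFP follows the marginal-FDR identity
$$\mathrm{PFP} = \frac{\pi_0 \alpha}{\pi_0 \alpha + (1 - \pi_0)\,
\mathrm{power}},$$ verified cell-by-cell against the power table in the
acceptance tests, and $E(\mathrm{FP}) = \pi_0 \alpha M$ both analytically
and by Monte-Carlo.

## The benchmark

At each $(\pi_0, \rho)$ grid point, `run_replicates()` simulates $R$
independent studies and feeds each study's p-values to all five
estimators, so all methods see identical data within a replicate — the
pairing that validates the subsequent paired t-tests. Accuracy is
summarised by the mean absolute error
$\mathrm{MAE} = \frac{1}{R}\sum_j |\hat\pi_0^{(j)} - \pi_0|$ (equal weight
to all errors) and, secondarily, RMSE ($\ge$ MAE by Jensen's inequality).
The reference method (ZG04) is compared with each competitor by a paired
two-sided t-test on absolute errors, and the point is labelled **blue**
(reference significantly best in all four comparisons), **red** (some
competitor significantly better), or **yellow** (otherwise) — a partition,
enforced by construction and by test.

The significance threshold is chosen from the experiment size: with
$G$ grid points and 4 tests each, a threshold $t$ keeps the expected
number of falsely declared significances $4Gt$ below one. The full-scale
default ($G \approx 190$) is $10^{-5}$; the scaled analysis scripts use
their own grid sizes and set $t = 0.01$ under the same rule, asserted in
the script. No further multiplicity correction is applied — the point of
the stringent threshold is that a declared difference is almost certainly
real.

Failed estimator runs are recorded as missing and excluded pairwise; a
point where any method fails on more than 10% of replicates is flagged
rather than labelled.

### Problem sizes

The package's own study runs at a deliberately desk-sized scale:
$M = 2{,}000$ genes, $R$ = 20–50 replicates per point and a handful of
grid points in the analysis scripts and acceptance checks ($M = 10{,}000$
is kept for single-experiment illustrations and the complete-null
Monte-Carlo). These sizes were chosen so the whole workflow re-runs in
minutes while leaving the Monte-Carlo standard errors of the reported MAEs
an order of magnitude smaller than the differences the benchmark
interprets. The qualitative conclusions — the median-slope estimator is
never significantly beaten near $\pi_0 = 0.8$, and the tail-based
estimators degrade gently with $\rho$ — are asserted at this scale in the
test suite; a full-resolution map (19 × 10 grid points, $R$ in the
hundreds, $M = 10{,}000$) uses the same code paths via
`sweep_parameter_space()` but is not re-run routinely.

## Degenerate inputs and numerical edges

* Zero pooled variance (probability zero under the model) is flagged:
  p = 1 if the condition means are equal, an error otherwise.
* ZG04 with no order statistic in $[t_1, t_2]$ errors and asks for a wider
  range; ST03 requires at least 4 grid points for the spline.
* Tied p-values: PC04 merges tied runs; the other estimators are
  unaffected. All estimators are invariant to input permutation.
* Estimates outside $[0, 1]$ are clipped and the clipping recorded in the
  estimate's diagnostics.

## What the simulation does not emulate

The generator produces normal expression with a single common variance,
equicorrelated blocks of one fixed size that never span the
null/alternative boundary, and one-signed effects around $d = 2$. Real
expression data have heavier tails, gene-specific variances, correlation
structures that are neither block-diagonal nor equicorrelated, and effect
sizes of both signs and varying magnitude. Passing this benchmark
therefore shows that an estimator handles upper-tail sparsity, boundary
bias and moderate positive correlation correctly — not that its accuracy
ordering transfers to any particular real data set. Distributional
robustness (non-normal expression, other test statistics) is out of scope;
the estimators only ever see p-values, so any valid test can be swapped in
upstream.
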