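---
title: "Data-driven qPCR normalization: model, uncertainty, and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven qPCR normalization: model, uncertainty, and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normagene)
```

## The problem

Relative qPCR expression values carry two distinct layers of variance within
a treatment. *Bias* is the among-replicate layer: differences in RNA
extraction yield, reverse-transcription efficiency, and general sample
handling shift **every** gene of a biological replicate by a common
multiplicative factor. *Variation* is the within-replicate layer: the
technical noise with which each individual gene is measured. Classical
practice divides all values by a reference ("housekeeping") gene, which
works only as well as the reference is stable and precisely measured — and
loses an entire biological replicate whenever its reference well fails.

`normagene` instead estimates the replicate-level bias from the target-gene
panel itself. Because the bias is shared by all genes of a replicate, a
panel of even modest size pins it down well, no reference gene is needed,
and a replicate missing any particular gene is never discarded.

## The estimator

Within one treatment, let $x_{ij}$ be the measured expression of gene
$i = 1..n$ in replicate $j = 1..m$, on the linear scale. The working model
on the log scale is additive:

$$\log x_{ij} = \mu_i + b_j + \varepsilon_{ij}, \qquad
  \varepsilon_{ij} \sim (0, \sigma^2_{\log x}),$$

with $\mu_i$ the gene's true mean log expression and $b_j$ the replicate's
log-scale bias. With $\hat m_i$ the mean of gene $i$'s present log values,
the bias is estimated by the closed form

$$\hat b_j = \frac{1}{N_j} \sum_{i \,\in\, \mathrm{present}(j)}
  \left(\log x_{ij} - \hat m_i\right),$$

where $N_j$ counts the genes recorded for replicate $j$. For complete data
this is exactly the least-squares solution of the additive model under the
identifiability constraint $\sum_j b_j = 0$; the test suite verifies the
agreement to $10^{-8}$ against an independent constrained fit. The
linear-scale normalization factor is $a_j = \mathrm{base}^{\,\hat b_j}$
(close to unity unless handling bias is severe), and normalization divides
it out: $x'_{ij} = x_{ij} / a_j$. Treatments are processed independently —
no between-treatment information is used, so up- or down-regulation cannot
leak into the factors and between-treatment differences are preserved
exactly.

**Unbalanced missing data.** With missing cells the closed form and the
exact unbalanced least-squares minimizer differ slightly. We keep the
closed form: it is what the estimator definition states, it needs no
iteration, and the gap (measured in the tests on a 6×4 grid with two
knockouts) is an order of magnitude below the noise scale and vanishes for
balanced data. Missing values are first-class masked cells, never imputed.

## Uncertainty of the fitted bias

Residuals of the fit pool into
$\hat\sigma_{\log x} = \sqrt{\sum r_{ij}^2 / \mathrm{df}}$ with
$\mathrm{df} = (\text{present cells}) - n - m + 1$, the residual degrees of
freedom of the additive model; this df choice makes $\hat\sigma^2$ unbiased
under the model (the single free residual of a complete 2×2 grid is the
hand-checkable base case). Variance homogeneity on the log scale — i.e.
equal *relative* error across genes — is assumed throughout.

The first-order sd of $\hat b_j$ is reported in two forms:

* **reduced** (the canonical output): $\sigma / \sqrt{N_j}$;
* **full**: $\sigma \sqrt{(1/N_j)\,(1 - 1/\bar M)}$, with $\bar M$ the
  harmonic mean of the per-gene replicate counts $M_i$ over the genes
  present in replicate $j$.

The full form is the exact least-squares variance in the balanced case
(verified against 10,000 noise-only simulations) and converges to the
reduced form as $\bar M \to \infty$; it is never larger. The reduced form
underlies the package's stability guidance: relative to a single gene the
sd shrinks as $1/\sqrt{n}$, is exactly halved at four genes and *more* than
halved from five genes on — hence the recommendation of panels of at least
five targets, enforced as a warning (not an error) when a replicate has
fewer than five present genes, since the estimate remains valid, merely
noisier.

When gene subsets of size $k$ are drawn from a fixed $n$-gene panel
(`subsample_stability()`), the across-subset sd of $\hat b_j$ follows
$\sqrt{1/k - 1/n}$ — the $1/\sqrt{k}$ law with the finite-panel correction
that makes it vanish when every gene is used. Subsets are drawn uniformly
without replacement with an explicit seed; per-replicate statistics are
computed first and then averaged, since any other aggregation would be an
arbitrary choice.

**Log base.** The default base is 10 (qPCR convention). The choice only
scales the reported $b_j$ and $\sigma$; the normalized linear-scale output
is base-invariant to floating-point tolerance, which the tests assert for
bases 2, 10 and $e$.

## The reference-gene baseline

For comparison, `reference_factor()` implements the classical strategy: the
per-replicate factor is the geometric mean of the designated reference
genes' present values (one gene reduces to its own value). Reference-gene
*selection* (stability ranking across candidates) is deliberately out of
scope — the baseline takes a validated reference set as given. A replicate
with no present reference value is flagged `lost` and dropped by
`apply_reference_normalization()` with a warning: this faithfully models
the structural weakness being benchmarked, not a defect to be glossed over.

## The artificial-data generator

`simulate_qpcr()` draws data in two independent seeded steps, mirroring the
two variance layers:

1. a replicate bias $\beta_j \sim N(0, \texttt{bias\_sd})$ on the natural
   log scale, shared by every gene of the replicate and drawn fresh for
   every re-sampling (the bias is experiment-dependent);
2. independent gene-level noise for each cell:
   $\log x = \texttt{true\_mean\_log} + \beta_j + N(0, s)$, with
   $s = \sqrt{\ln(1 + \mathrm{cv}^2)}$ for targets and $s$ scaled by
   `ref_cv_ratio` for the reference channel.

The defaults are the benchmark's study conditions: one treatment, 4
replicates, 8 target genes at 10% coefficient of variation, 1 reference
channel, true log mean 0 (relative expression 1), 40 re-samplings per
condition. Noise is normal on the log scale (lognormal values) because the
estimator works on logs and the variance-homogeneity assumption is about
relative error; the "10%" knob is read as a linear-scale CV and converted
by `cv_to_log_sd()` — at this magnitude the CV and log-sd readings differ
by under 0.5%, so nothing downstream is sensitive to the choice. The
reference channel has a *perfect* true mean (no between-treatment
instability); only its measurement precision varies. That makes the
benchmark conservative in favor of the reference method: real references
are rarely this clean.

Seeding: each (condition, resample) pair receives a deterministic 32-bit
substream seed derived from the master seed, so every scan is exactly
reproducible from one integer.

What the generator does **not** emulate: amplification-efficiency
estimation upstream of relative quantification, outliers (the least-squares
fit is not robust to them; quality control belongs upstream),
between-treatment effects, and correlated noise between genes. Passing
benchmarks therefore demonstrate behavior under the additive lognormal
model, not under arbitrary real-data pathologies.

## Benchmark metrics and design choices

Two normalizations of the same simulated cells are compared against the
known truth:

* `variance_reduction()` — $1 - \mathrm{RSS}_{\text{norm}} /
  \mathrm{RSS}_{\text{raw}}$, where RSS is the sum of squared deviations of
  log values around their per-gene means within the treatment. For the
  data-driven fit this is non-negative by the least-squares property. Under
  the additive model its expectation is
  $1 - \frac{n-1}{n} \cdot \frac{1}{1 + r^2}$ at bias-to-variation ratio
  $r$, so with $n = 8$ it rises from about 0.18 at $r = 0.25$ through 0.50
  at $r = 1$ toward its asymptote $1$. An alternative metric family —
  reduction of the *among-replicate* (replicate-mean level) variance, with
  expectation $r^2/(r^2 + 1/n)$ — saturates much faster (0.89 at $r = 1$)
  but can be strongly negative for small bias and is not least-squares
  guaranteed; we report the pooled-residual definition because its
  guarantee matches what the normalization actually minimizes.
* `closeness_proportion()` — the fraction of cells whose normalized log
  value lies strictly nearer the true mean than the competitor's, ties
  scoring one half ("data points closer to the true mean"; 0.5 means equal
  performance). Measured per cell on the log scale, where the model and the
  normalization both live.

`run_bias_scan()` sweeps the bias-to-variation ratio over
$\{0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4\}$; `run_precision_scan()` sweeps the
reference-to-target precision ratio over $\{1, 0.75, 0.5, 0.33, 0.25,
0.175\}$ at a fixed bias level. The fixed bias-to-variation ratio of the
precision scan defaults to 0.75, the midpoint of the 0.5–1.0 range typical
of real qPCR data-sets; it is exposed as an argument. Crossings of the 0.5
equal-performance level are located by linear interpolation between the
two bracketing grid points (`find_crossover()`); with the default design
the two methods break even near bias-to-variation ratio 2, and the
reference route needs roughly four-fold extra measurement precision to tie
at the default bias level. Exact ties in the closeness comparison have
probability zero under the model; the 0.5 credit is a tie-break
convention, not a tuning knob.

Paired method comparisons (e.g. per-resample variance reductions of the two
routes) use Wilcoxon's signed-rank test via `wilcoxon_compare()`: exact
null distribution up to 25 pairs, continuity-corrected normal approximation
above; an all-ties comparison is degenerate and returns $p = 1$ with a
warning rather than an error.

## Problem sizes

The shipped test suite and the results-reproduction script size their
simulations as follows, chosen to keep Monte-Carlo error well inside each
asserted tolerance: 400 re-samplings per condition for the two crossover
scans, 200 for the variance-reduction monotonicity check, 10,000 noise-only
fits for validating the full-form bias sd (3% tolerance), and 1,000–4,000
draws for the smaller consistency checks.

## Known limitations

* The closed-form estimator is not the exact least-squares solution under
  unbalanced missingness (see above); the difference is quantified, not
  hidden, and irrelevant for balanced panels.
* Least squares is sensitive to outliers; no robust (median-based) variant
  is provided. Verify amplification quality upstream.
* Between-treatment normalization is out of scope by design: factors are
  strictly within-treatment.
* With fewer than five present genes in a replicate the factor is noisy;
  the package warns but proceeds.
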