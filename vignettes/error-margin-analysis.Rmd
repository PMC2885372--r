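---
title: "Error-margin analysis for feature gene extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-margin analysis for feature gene extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emargin)
```

## The problem

Two-class expression studies (tumour versus normal) routinely need a
*panel* of feature genes: the genes whose expression separates the
classes, free of the background genes that do not. Filter methods rank
genes by a per-gene statistic and cut the list at a significance
threshold; wrapper methods optimize a classifier-derived objective.
Both leave the *number* of genes to a tuning parameter, and objectives
based on training accuracy are unreliable when there are thousands of
genes and only tens of samples.

`emargin` implements a margin-based alternative. The geometric margin
of a maximum-margin linear classifier — the distance from the decision
hyperplane to the nearest training pattern — measures the confidence of
the separation. Under two working assumptions (genes are independently
expressed; class-conditional expression is Gaussian), the expected
margin of a classifier built on a gene subset behaves like a weighted
sum of the class-mean differences of the included genes. Feature genes
have large class-mean differences, background genes near-zero ones: so
as genes are added in order of decreasing relevance, the margin grows
quickly while true features are being added and slowly once only
background genes remain. The number of feature genes is the *critical
point* — the kink — of that curve.

## The procedure

Given a dataset of $n$ samples over $d$ genes with labels
$y_j \in \{-1, +1\}$:

1. **Relevance ranking.** Each gene gets a two-sided two-sample t-test
   p-value between the classes; the relevance list $L$ orders genes by
   ascending p-value (relevance $r = 1 - p$), ties broken by the
   original gene index. The classical pooled-variance test is the
   default — it is the conventional "t-test" of the microarray filter
   literature — with Welch's variant behind a flag.
2. **Leave-one-out error-margin curve.** For each $i = 1..f_{\max}$,
   restrict the data to the $i$ most relevant genes and compute the
   *leave-one-out error margin*: for each sample $j$, fit a soft-margin
   linear SVM to the other $n-1$ patterns and take the geometric margin
   of that hyperplane over those same patterns; average the $n$ fold
   margins. This is $W(i)$.
3. **Critical point.** For every candidate breakpoint $c$, fit two
   order-$\gamma$ polynomials to $W$ — one over $i \le c$, one over
   $i > c$ — by least squares, constrained to meet at $c$. The
   estimated gene count $f_0$ is the $c$ minimizing the residual sum of
   squares $\varepsilon(c)$, and the selected panel is the top $f_0$ of
   $L$.

```{r example, eval = FALSE}
sets <- generateSynthetic(seed = 1)     # 25 train / 475 validation samples
res  <- extractFeatures(sets$train)     # rank -> curve -> breakpoint
featureSize(res$features)
validationAccuracy(sets$train, sets$valid, res$features)
```

## Tunable parameters

* `fMax` (default 100): the number of curve points, i.e. the prior
  upper bound on the panel size. It only needs to comfortably exceed
  the plausible number of features; curve points beyond the breakpoint
  stabilize the irrelevant-segment fit.
* `degree` ($\gamma$, default 2): the polynomial order of each segment.
  Order 2 captures the mild concavity of measured curves without
  chasing their noise; it is also the default model order used in the
  benchmark this package replicates.
* `cost` (C, default 1): the soft-margin penalty of every SVM fit —
  the conventional default of SVM implementations (libsvm,
  scikit-learn, and the MATLAB toolboxes all default to a box
  constraint of 1). On the unit-scale synthetic benchmark the selection
  statistics are nearly insensitive to C over 1–100; with large C,
  separable folds approach the hard-margin optimum exactly, which the
  test suite exploits. The margin of a non-separable fold is measured
  over its correctly classified patterns only.
* `cutoff` (default 0.005): the p-value threshold of the t-test filter
  baseline `ttestFilter()` — the classical filter the margin criterion
  is compared against. The threshold is strict (`p < cutoff`).

## Numerical choices

* **Margin normalization.** All margins are geometric:
  $y_j(\langle h, x_j\rangle + b)/\lVert h \rVert$, minimized over the
  pattern set. This is the only scale-invariant choice, and it is
  invariant to translating all patterns — so no centering or clipping
  of the data is needed.
* **Hyperplane orientation.** The underlying libsvm solver signs its
  decision values by factor-level order; fits are re-oriented so that
  correctly classified patterns always have positive functional margin.
* **Degenerate folds.** A leave-one-out fold whose remainder is
  single-class, or classifies nothing correctly, has no defined margin;
  such folds are skipped and the fold average is over the valid folds
  (they are counted and reported). With the benchmark's 25-sample,
  near-balanced training sets no fold is ever degenerate.
* **Constraint handling.** The continuity constraint is eliminated by
  substituting the irrelevant-segment intercept
  $D = G(c \mid A, B) - \sum_k C_k c^k$, leaving an ordinary linear
  least-squares problem solved by QR — algebraically the normal-equation
  solve for the joint coefficient vector. The unit tests verify
  equivalence against an explicit Lagrange-multiplier solver.
* **Well-posedness and ties.** Candidates leaving fewer than
  $\gamma + 1$ points in either segment are excluded (both polynomials
  must be identifiable), so the scan runs over
  $[\gamma + 1, f_{\max} - \gamma]$. Exact ties in $\varepsilon$ —
  e.g. a curve that one global polynomial fits, where every candidate
  is equally good — resolve to the smallest candidate (parsimony), with
  a relative tolerance of $10^{-10}\sum_i W(i)^2$ so that
  machine-rounding differences between exact ties do not defeat the
  rule.

## The synthetic benchmark generator

`generateSynthetic()` reproduces the controlled conditions under which
the method's selection behaviour is measured: 500 genes, of which genes
1–20 are true features drawn from class-conditional Gaussians with
means $\mu_i = 0.3 - 0.05i/20$ (negative class) and
$\alpha_i = 0.7 - 0.05i/20$ (positive class) and common SD
$0.15 - 0.05i/20$ — a constant class difference of 0.4 with spread
shrinking in $i$ — and genes 21–500 are Uniform(0, 1) background for
both classes. Each run yields 25 training and 475 validation samples,
near-balanced (13/12 and 237/238). The uniform background support
$[0, 1]$ matches the unit scale of the feature-gene means and is
configurable. Gaussian draws are not clipped: the method is
translation-invariant, so occasional negative "expression" values are
harmless.

What the generator does *not* emulate: probe- and batch-level artifacts
of real microarrays, gene–gene correlation, heavy-tailed expression.
Passing the benchmark therefore demonstrates correct behaviour under
independent-gene, Gaussian-vs-uniform conditions — the regime in which
the margin-curve argument is derived — not performance on real chips.
`generateIdealCurve()` additionally produces piecewise-linear margin
curves with a known breakpoint (plus optional Gaussian oscillation) for
isolating the breakpoint estimator from the margin machinery.

## Replication protocol and problem sizes

`runSyntheticBenchmark()` repeats the experiment over independent runs
(default 100; per-run seed = base seed + run index so any run can be
replayed alone) and aggregates: mean/SD/median/min/max of the selected
count, mean true-feature count, hitting rate $r_h = f_A/20$, redundancy
rate $r_m = (f - f_A)/f$, and validation accuracy of a linear
max-margin classifier refit on the selected genes (same C as the
pipeline). `runSubsampleBenchmark()` implements the sampling-rate
protocol used for real datasets: stratified training subsets of rate
$r$ per class (floor rounding, minimum 2 per class), validated on the
complement or on a fixed hold-out set.

The unit suite exercises the same machinery at reduced sizes (tens of
genes, 12–16 samples, a dozen seeds) so the default test run stays
fast; the acceptance script and the acceptance tests run the full
100-run, 500-gene protocol.

## Observed behaviour and limitations

On the synthetic benchmark the t-test filter at cutoff 0.005 selects
all 20 features plus the expected $480 \times 0.005 \approx 2.4$
background false positives per run. The margin-curve criterion needs no
threshold, but its breakpoint estimate inherits the sharpness of the
curve's kink: in 24-sample leave-one-out folds each added background
gene still enlarges the attainable margin slightly (small-sample mean
differences accumulate), so the measured curve keeps rising past the
true boundary, the $\varepsilon(c)$ valley is shallow, and the
estimated count scatters run to run, landing a few genes above the
planted 20 on average (the 100-run replication protocol reports the
exact figures). Selection quality should therefore be judged by the
aggregate hitting/redundancy rates, not by single-run counts.

Known limitations: linear margins only (nonlinear kernels are out of
scope); exactly two segments with a fixed polynomial order (no model
selection for $\gamma$); two classes only; the t-test ranking treats
genes marginally, so complementary gene *pairs* with weak marginal
effects rank low.
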