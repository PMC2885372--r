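# emargin

Feature gene extraction for two-class expression data by **error-margin
analysis**: instead of cutting a ranked gene list at a significance
threshold, the number of feature genes is read off the *error-margin
curve* — the leave-one-out geometric margin of a linear maximum-margin
classifier as a function of how many of the most relevant genes are
included.

## The method

Given samples $x_j \in \mathbb{R}^d$ with labels $y_j \in \{-1, +1\}$:

1. **Rank** genes by two-sided two-sample t-test p-value between the
   classes (pooled variance by default); the relevance list $L$ orders
   genes by ascending $p$.
2. **Curve.** For $i = 1..f_{\max}$, restrict the data to the $i$ most
   relevant genes and compute the leave-one-out error margin
   $W(i)$: for each left-out sample, fit a soft-margin linear SVM to
   the remaining patterns and take the geometric margin
   $\min_j y_j(\langle h, x_j\rangle + b)/\lVert h\rVert$ over those
   patterns (correctly classified ones when the fold is not
   separable); average over folds.
3. **Critical point.** For each candidate breakpoint $c$, fit two
   order-$\gamma$ polynomials (default $\gamma = 2$) to the curve — one
   for $i \le c$, one for $i > c$ — by least squares constrained to
   meet at $c$, yielding a residual $\varepsilon(c)$. The estimated
   number of feature genes is $f_0 = \arg\min_c \varepsilon(c)$, and
   the panel is the top $f_0$ of $L$.

The rationale: the expected margin grows like a weighted sum of
class-mean differences of the included genes, so it rises steeply while
informative genes are added and slowly after — $f_0$ marks the kink.
No p-value cutoff or panel size needs to be chosen in advance.

The package also ships the classical t-test filter baseline
(`ttestFilter`, select $p <$ cutoff), a synthetic two-class benchmark
generator with 20 Gaussian feature genes and 480 uniform background
genes, and the replication protocols (100-run synthetic benchmark,
sampling-rate subsampling).

## Worked example

```r
library(emargin)

sets <- generateSynthetic(seed = 2)   # 25 train / 475 validation samples
sets$train
#> ExpressionDataset: 25 samples x 500 genes
#>   classes: 12 negative (-1), 13 positive (+1)

res <- extractFeatures(sets$train)    # rank -> LOO margin curve -> breakpoint
res$features
#> FeatureSet of 24 genes
#>   gene20, gene16, gene14, gene19, gene17, gene13, gene18, gene8...

hitMissRates(res$features, truth = 1:20)[c("fA", "hitRate", "missRate")]
#> $fA       [1] 20
#> $hitRate  [1] 1
#> $missRate [1] 0.1666667

validationAccuracy(sets$train, sets$valid, res$features)
#> [1] 1
```

Here the breakpoint search put the critical point at 24 genes: all 20
planted feature genes are recovered (hitting rate 100%) along with 4
background genes (redundancy 17%), and a linear classifier on the
panel classifies all 475 held-out samples correctly — typical behaviour
for this benchmark, where the margin curve's kink is smeared over a few
genes by sampling noise. `res$curve` holds $W(1..100)$ and
`res$profile` the $(c, \varepsilon)$ scan, which `writeReport()` writes
as TSV/JSON alongside the gene list.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/ema.R` (`simulate`, `rank`, `curve`, `extract`, `ttt`,
`bench` subcommands).

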