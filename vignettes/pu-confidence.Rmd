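---
title: "Assessing confidence in positive-unlabeled learning by permutation testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing confidence in positive-unlabeled learning by permutation testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puconfide)
```

## The problem

In positive-unlabeled (PU) learning only one class is ever labeled: a set
of known positives (KP) sits inside a larger unlabeled set (U) that mixes
hidden true positives (TP) and true negatives (TN). Vaccine-trial
correlates analysis is a typical example: infected subjects are definitive
positives, but uninfected subjects mix protected and simply-unexposed
individuals. Because no negative examples exist, accuracy, F1 or MCC
cannot be computed — and a transductive PU classifier will rank the
unlabeled samples *whether or not* the data contain any class structure.
puconfide supplies the missing negative control: it asks how often the
observed performance on the known positives would arise if the positive
labels carried no information, by rebuilding the entire scoring pipeline
under random label permutations.

## The procedure

**PU bagging.** The transductive bagging strategy draws, in each of $T$
rounds, $|KP|$ unlabeled samples with replacement as temporary negatives,
fits a classifier on all KP (class 1) against the bag (class 0), and
predicts every out-of-bag (OOB) unlabeled sample. A sample's score is

$$\mathrm{score}_i \;=\;
  \frac{\#\{\text{rounds OOB and predicted class 1}\}}
       {\#\{\text{rounds OOB}\}},$$

the fraction of its OOB rounds won by class 1. Scores aggregate *hard*
per-round predictions (votes), not per-round probability estimates. The
default classifier is an RBF-kernel SVM with library-default
hyperparameters — deliberately untuned, because the PU setting offers no
labels to tune against, and the bagging score is largely insensitive to
the choice of base classifier. With `scale_on_bag = TRUE` (default), each
round standardizes features using the in-bag rows only; constant features
get a unit divisor.

**Spy scoring of the positives.** To score the KP set itself, each repeat
partitions KP into $K$ folds (sizes differing by at most one) and moves
one fold at a time into U as "spies"; PU bagging then scores the spies
with the remaining KP as positives. Pooling the $K$ folds gives one score
per KP sample per repeat, summarized two ways:

* **EPR** (explicit positive recall): the fraction of spy scores
  *strictly* exceeding 0.5 — a score exactly at the threshold does not
  count;
* **MBS** (mean bagging score): the plain mean, threshold-free. MBS
  typically shows lower between-repeat variance than EPR (logged as a
  diagnostic, not asserted: the relation is empirical, not guaranteed).

$R$ repeats with different fold splits (default 30) characterize the
variance of both metrics.

**Permutation null.** The positive labels are reassigned to a uniformly
random subset of *all* samples (count preserved; permuted positives may
land on true negatives) and the spy procedure is rerun. Each of the $B$
permutations contributes one null draw of EPR and MBS. By default a
single spy repeat runs inside each permutation — $B$ null draws at
$B$-fold cost; `n_repeats_per_permutation` raises this when a
smoother per-permutation estimate is wanted.

**Comparison statistics.** With $\mu$ the mean actual-label score over
the $R$ repeats, $\mu_0$ the null mean, and $\sigma$ the null standard
deviation ($n-1$ degrees of freedom),

$$z = \frac{\mu - \mu_0}{\sigma},$$

tested upper-tailed ($\mu > \mu_0$): only better-than-chance performance
can be significant. Cliff's Delta between the $R$ actual scores and the
$B$ null draws quantifies the effect size, with the conventional
magnitude boundaries $0.147/0.33/0.474$ (negligible/small/medium/large)
and a 95% confidence interval from Cliff's consistent variance estimate
with the asymmetric transformation, clamped to $[-1, 1]$. p-values for
EPR and MBS are reported raw, without multiple-testing adjustment.
When ground truth is available (synthetic benchmarks), the **U-AUC** —
rank-based ROC-AUC between U-set bagging scores from a dedicated full-KP
run (no spies removed) and the hidden labels, ties counting one half —
says how well the ranking actually recovered the hidden classes.

## The synthetic generator

`generate_synthetic()` emulates the standard hypercube construction used
by common machine-learning toolkits: each class is a Gaussian cluster at
a class-specific vertex of a $[-d, d]$ hypercube in the
informative-feature subspace (defaults: 30% informative features),
passed through a class-specific random linear map with entries uniform
on $[-1,1]$; redundant features (70%) are exact random linear
combinations of the informative block; any remainder is independent
noise. `relabel_pu()` then reveals `n_kp` random true positives as KP.

Two consequences deserve emphasis:

* Because each class owns its random covariance transform, the classes
  remain partially separable even at $d = 0$, where only their means
  coincide. A U-AUC modestly above 0.5 at zero separation is therefore a
  property of the generator, not a bug in the scoring.
* No label noise is applied: class counts follow `tn_proportion`
  exactly (rounded to nearest, remainder to the positive class), and at
  high separation the U-AUC can reach 1.0.

One cluster per class is used; fractional fractions are rounded; the
generated matrix has TP rows first, then TN. The generator reproduces
bit-identically from its seed.

What the generator does *not* emulate: batch effects, heavy-tailed or
discrete features, missing values, correlated noise, or biased selection
of the known positives (real KP sets are rarely uniform draws from the
positive class). Passing tests on synthetic data therefore demonstrate
the statistical machinery, not robustness to every pathology of real
profiling data.

## Numerical and design choices

* **Seeding.** One master seed drives everything through a counter-based
  derivation (`derive_seed(master, stream, index)`), so generation,
  relabeling, each bootstrap round, each fold split and each permutation
  consume independent reproducible streams; results are invariant to
  execution order, and permutations could be evaluated in parallel
  without changing any number.
* **Never-OOB samples.** A U sample missed by all $T$ bags (probability
  vanishing at $T = 100$) gets the neutral score 0.5 plus a warning,
  keeping downstream ranking defined rather than failing the run.
* **Degenerate nulls.** If all permutation draws coincide
  ($\sigma = 0$), `z_test()` stops with an explicit error instead of
  reporting an infinite z.
* **Strict EPR threshold.** `epr()` uses `score > threshold`; with
  $T = 100$ bootstraps, scores of exactly 0.5 occur and the strictness
  is visible in the result.
* **Spy runs score only the spies by default.** Per-row SVM predictions
  are independent, so restricting prediction to the spy fold
  (`score_only`) produces bit-identical spy scores while skipping wasted
  work; `keep_u_scores = TRUE` retains the full U-set diagnostics.
* **Defaults** ($K = 5$, $R = 30$, $B = 30$, $T = 100$, threshold 0.5)
  are the study conditions under which the method was characterized. The
  z-test p-value is stable in $B$ over 30–500, so the default favours
  the cheap end.

## Problem sizes used in the test suite

The package's own checks run the full conditions where they are cheap
(U-AUC benchmarks at $n = p = 200$, $T = 100$, medians over 10
generations) and scaled-down designs where the full ones would be
wasteful on a laptop: the null-calibration check uses
$n = 100,\ p = 50,\ R = 5,\ B = 20,\ T = 50$ over tens of replicates,
and the permutation-count stability check uses $T = 20$ with
$B \in \{30, 100, 500\}$. These sizes are the package's chosen test
conditions; the assertions (rejection rate at most 5% on structureless
data, p-value stability within an order of magnitude, no opposite
crossings of 0.05) are unchanged by the scaling.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(n_samples = 200, n_features = 200,
                        class_sep = 2, tn_proportion = 0.5, seed = 1)
pu <- relabel_pu(generate_synthetic(cfg), n_kp = 40, seed = 1)
fit <- pu_confidence(pu, seed = 1)   # K=5, R=30, B=30, T=100
fit$report
```

At high separation both metrics sit far above their nulls (large
Cliff's Delta, tiny p), and the U-AUC confirms the ranking is real. At
`class_sep = 0` the same report shows p-values scattered uniformly and
negligible-to-small effect sizes: the gatekeeper refuses the model.

## Limitations

The method controls the *no-information* baseline; it cannot certify
that a significant model is unbiased, and with very few true negatives
among U (about 10%) real class structure can go undetected — the spy
scores of actual and permuted positives approach each other even when
ground-truth separation exists. It is transductive: scores apply only to
the samples present at modeling time. And a single PU strategy (bagging
with OOB votes) is implemented; other PU approaches may respond
differently to permutation.
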