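---
title: "Knowledge-guided feature selection with the GIS-weighted LASSO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-guided feature selection with the GIS-weighted LASSO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gislasso)
```

## The problem

LASSO-regularized generalized linear models are the workhorse of embedded
feature selection on gene expression data, but they treat every gene as
equally plausible a priori. When groups of genes are highly correlated —
ubiquitous in transcriptomics because of co-expression — the L1 penalty
picks among them arbitrarily, and the selected signature may be hard to
interpret biologically. `gislasso` biases that choice with prior knowledge:
it distils what ontologies (GO- or HPO-like DAGs) already record about each
gene into a single score, and turns the score into a per-gene penalty so
that better-characterized genes are shrunk less. Selection still has to be
earned through predictive power; the prior only modulates it.

## The score chain

**Term information content.** For a term $t$ in an ontology $k$ structured
as a DAG, with $depth(t)$ the longest path from any root (roots at depth
0), $desc(t)$ its number of distinct descendants, and $max\_depth_k$,
$total\_terms_k$ the ontology-wide statistics over non-obsolete terms:

$$IC_{struct}(t) = \frac{depth(t)}{max\_depth_k}\left(1 -
  \frac{\log(desc(t)+1)}{\log(total\_terms_k)}\right).$$

Deep, specific terms score high; roots score exactly 0; a childless term at
the maximal depth scores exactly 1. Both factors are normalized so scores
from different ontologies are commensurable, and the log ratio is invariant
to the logarithm base (we use the natural log). The DAG edges considered
are configurable (`relationships`, default `is_a` + `part_of`): real
ontologies carry many relationship types, and which ones constitute "the"
hierarchy is a modelling choice, not a property of the file.

**Gene Information Score.** Each gene's most-specific annotations are
*unfolded*: replaced by their full ancestor closure in the DAG (including
the direct term itself — the most specific term carries the highest
information content, and dropping it would discard exactly the strongest
signal). The binary gene-by-term matrix $B$ over the pooled terms of all
supplied ontologies is reweighted entrywise by $IC_{struct}$ to give $W$,
and

$$GIS(g) = \frac{\sum_{m:\,W_{g,t_m}>0} W_{g,t_m}}{\sum_{m:\,W_{g,t_m}>0} 1}$$

is the mean information content of the gene's annotation closure, in
$[0,1]$. The $0/0$ case — a gene with no positive entries — is defined as
$GIS = 0$: no prior biological information. The pooled mean deliberately
weights ontologies by how many terms they contribute; a per-ontology
breakdown for diagnostics is available by building matrices per ontology.

**Penalty transform.** Relevance must *lower* the penalty, so the score is
passed through the decreasing one-parameter family

$$wGIS(g) = \frac{1}{1 + s \cdot GIS(g)},$$

implemented as `gis_penalty(gis, shape = s)`. The canonical member $s = 1$
maps $[0,1]$ onto $[0.5, 1]$: an unknown gene gets the full penalty, a
maximally-annotated gene half of it. $s = 0$ collapses every penalty to 1 —
the standard LASSO — which makes the shape parameter a continuous dial
between "ignore the prior" and "trust it strongly", tunable jointly with
$\lambda$ in `cv_wlasso()`.

## The weighted LASSO solver

`wlasso()` minimizes

$$\frac{1}{n}\sum_{i=1}^n\left[b(\eta_i) - y_i\eta_i\right] +
  \lambda \sum_{j=1}^q w_j\,|\beta_j|, \qquad \eta_i = \beta_0 + x_i^\top\beta,$$

with $b$ the log-partition function (gaussian: half squared error;
binomial: $\log(1+e^{\eta})$) and $w_j \ge 0$ the penalty factors. The
penalty is on the absolute values — the L1 reading — and the intercept is
never penalized. The solver is cyclic coordinate descent with per-feature
soft thresholds $\lambda w_j$; the binomial family wraps it in an outer
IRLS quadratic approximation (glmnet-style), with a backtracking step that
only ever accepts iterates that do not increase the true penalized
objective, so the recorded `objective_path` is non-increasing for both
families. Cyclic (fixed-order) updates make tie-breaking among duplicated
features deterministic. Unit penalties reproduce the standard LASSO, which
the test suite verifies against `glmnet` to `1e-5`; for general weights the
principal correctness oracle is the rescaling identity: fitting the
standard LASSO on columns $x_j / w_j$ and dividing the coefficients by
$w_j$ minimizes the same objective as the direct weighted fit.

Numerical choices:

* **Standardization** (default on): columns are centered and scaled to unit
  population variance before fitting; coefficients are reported on the
  original scale. Zero-variance columns are excluded from penalized fitting
  with a warning and get coefficient 0. With `standardize = FALSE` the
  penalty applies to raw-scale coefficients (the setting the rescaling
  oracle requires).
* **Convergence**: `tol = 1e-6` on the maximum absolute coefficient change
  per sweep, `max_sweeps = 10000` in total. Near-duplicate columns create a
  nearly flat ridge along which coordinate descent moves slowly; the
  objective value and the selected set stabilize long before the
  coefficients do, so the simulation harnesses run with a larger sweep
  budget and a looser tolerance, and report how many fits stopped at the
  budget rather than warning per fit.
* **KKT certificates**: `kkt_check()` verifies
  $|\nabla_j \ell| \le \lambda w_j$ (with equality at active coordinates)
  on the scale the optimizer ran on, and is asserted throughout the tests.

**The $\lambda$ scale.** The loss above is scaled by $1/n$, and `lambda`
is on that scale by default (`lambda.scale = "mean"`), matching `glmnet`.
Some platforms instead penalize against the *summed* loss; their printed
$\lambda$ corresponds to $\lambda/n$ here (`lambda.scale = "sum"`). The
distinction matters: for the binomial family with standardized features the
null-model gradient is bounded by roughly $0.4$, so on the mean scale any
$\lambda \ge 0.5$ provably yields the empty model, whereas the conventional
$\lambda$ values $0.2$–$1.0$ quoted for the multicollinearity protocol
below are active and meaningful on the sum scale. The simulation harnesses
therefore default to `lambda.scale = "sum"`; the fitting functions default
to `"mean"`. Both conventions are reachable everywhere.

**Cross-validation.** `cv_wlasso()` grid-searches $(\lambda, s)$ with
stratified folds for classification, scoring accuracy (classification) or
MSE (regression). Exact metric ties break toward the larger $\lambda$ —
the sparser model — and then the smaller shape; parsimony is the rationale.
**Multiclass** labels are handled one-vs-rest (`wlasso_ovr()`), predicting
by maximal linear score; one-vs-rest is a conventional default and is
recorded in the pipeline report rather than silently assumed.

## The synthetic-data module

The generators emulate the three inputs end to end, so every protocol runs
without downloads:

* `sim_ontology()` grows a single-root DAG whose backbone chain pins the
  height and whose occasional second parents create the multi-parent
  diamonds that make closure-counting nontrivial.
* `sim_annotations()` draws most-specific terms biased toward deep terms
  (probability $\propto (depth+1)^2$) with a $1+\mathrm{Poisson}$ count per
  gene, and leaves an exact fraction of genes unannotated so $GIS = 0$
  genes exist by construction.
* `sim_expression()` draws independent standard-normal features — a
  stand-in for standardized expression profiles — and labels from a
  zero-intercept logistic model, balanced in expectation. Noise is added to
  features on this standardized scale throughout.

What the generators do *not* emulate: correlated co-expression blocks
(beyond the explicit noisy copies), heavy-tailed count noise, batch
effects, and any dependence between a gene's annotation richness and its
predictive power. Passing tests therefore demonstrate the mechanics of the
method — scores, penalties, selection behavior — not performance on real
sequencing data.

## The sensitivity protocols

**Controlled dataset.** `controlled_dataset()` selects seed features
spanning the Fisher's-score range (quantile strata; within each stratum the
most discriminative feature that respects the pairwise correlation cap
$|r| < 0.5$), then randomly fills with features at $|r| < 0.5$ to the seeds
and $|r| < 0.7$ among themselves. Fisher's score uses maximum-likelihood
class variances; degenerate zero-within-class-variance features score
`Inf` with a warning.

**Multicollinearity** (`run_multicollinearity()`): the designated feature
gets 10 copies plus $N(0, 0.01^2)$ noise; five penalty scenarios (NO_GIS,
GIS1–GIS4) assign the block penalties, with the ladder scenarios evenly
spaced inclusive of endpoints and the smallest penalty on copy 1 (the
ordering is a free choice and is recorded in the result metadata). Outside
NO_GIS the original keeps its own penalty, and non-block features keep
their baseline penalties (their own wGIS when supplied, 1 otherwise).
Each of the 100 repetitions regenerates the noise with a counter-derived
seed shared across scenarios and $\lambda$ values, so comparisons are
paired. The acceptance-scale run uses 144 samples and a 60-feature
controlled subset (5 seeds + 55 fillers, caps as above) with the strongest
feature duplicated — sizes chosen to keep the 100-repetition protocol at
desk scale while leaving $n$ above the feature count.

**Predictive power** (`run_predictive_power()`): penalty overrides emulate
incomplete or erroneous priors. Repetitions need fresh randomness, and a
fixed matrix has none, so each repetition redraws a dataset from the
generator parameters stored on the `sim_expression()` object. Two
properties are asserted: lowering a predictive feature's penalty never
decreases its coefficient magnitude at fixed data and $\lambda$, and a
zero-signal feature at the minimal penalty 0.5 stays unselected (at most
5% of 100 repetitions) at a moderate mean-scale $\lambda$ of 0.15 — large
enough that the soft threshold sits well above the null-gradient noise
floor at $n = 200$.

## Degenerate inputs and edge policies

Singleton or flat ontologies (fewer than 2 terms, or maximal depth 0) are
rejected by `ic_struct()` rather than silently scored 0. Obsolete terms are
excluded everywhere; annotations to them follow `replaced_by` when present
and are dropped with a warning otherwise. Unfolding is idempotent.
Annotation rows that do not parse are skipped with a counted warning; a
file with no usable rows is an error. Genes present in the expression
matrix but absent from the annotations receive $GIS = 0$ and the maximal
penalty 1. Cross-validation folds are stratified with a rotating counter so
overall fold sizes differ by at most one; a training fold with a single
class triggers refolding with a warning.

## Limitations

The information content is purely structural: it sees where a term sits in
the DAG, not how reliable or specific the annotation evidence is
(evidence-code weighting is accepted as a filter list but defaults to
keep-all). The score grows with annotation coverage, so well-studied genes
are systematically favored — that is the intended behavior, but it imports
the literature's attention bias. Ridge and elastic-net penalties, survival
families, and empirical-Bayes penalty learning are out of scope.
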