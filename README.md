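# gislasso — knowledge-guided feature selection with a GIS-weighted LASSO

`gislasso` is an R package for selecting genes from expression data while
trading off predictive power against prior biological knowledge. It turns
what ontologies (GO- or HPO-like DAGs) already record about each gene into
a per-gene **Gene Information Score (GIS)** and uses it as a
feature-specific L1 penalty in a weighted-LASSO generalized linear model,
so that among equally predictive (often highly correlated) genes the
better-characterized ones are preferred. It is aimed at transcriptomics
analysts (bulk or single-cell) who want interpretable sparse classifiers
or regressions rather than arbitrary picks from co-expressed blocks.

## The method

For a term $t$ of an ontology with maximal depth $D$ and $T$ non-obsolete
terms, the structure-based information content is

$$IC_{struct}(t) = \frac{depth(t)}{D}\Bigl(1 - \frac{\log(desc(t)+1)}{\log T}\Bigr) \in [0,1],$$

with $depth$ the longest root-to-term path and $desc$ the number of
distinct descendants. Each gene's most-specific annotations are unfolded to
their full ancestor closure; the binary gene-by-term matrix $B$ is
reweighted entrywise by $IC_{struct}$ to give $W$, and

$$GIS(g) = \frac{\sum_{m:\,W_{g,t_m}>0} W_{g,t_m}}{\sum_{m:\,W_{g,t_m}>0} 1} \in [0,1]$$

(0 for genes with no prior information). Scores become penalties via
$wGIS(g) = 1/(1 + s\,GIS(g))$, which for the default shape $s=1$ maps into
$[0.5, 1]$, and the model minimizes the penalized GLM objective

$$\frac{1}{n}\sum_i \bigl[b(\eta_i) - y_i \eta_i\bigr] + \lambda \sum_j wGIS_j\,\lvert\beta_j\rvert$$

by cyclic coordinate descent (gaussian and binomial families, IRLS outer
loop for the latter, one-vs-rest for multiclass). Unit penalties recover
the standard LASSO exactly.

## Worked example

```r
library(gislasso)

ont  <- sim_ontology(200, depth_target = 8, seed = 1)   # toy GO-like DAG
ont
#> Ontology 'simont': 200 terms, max depth 14
#>   relationships: is_a, part_of
#>   roots: 1; leaves: 90

genes <- paste0("g", 1:50)
ann  <- sim_annotations(genes, ont, frac_unannotated = 0.2, seed = 2)
am   <- annotation_matrices(ann, ont)       # sparse B and W
gis  <- gene_information_score(am)
round(head(gis), 3)
#>    g1    g2    g3    g4    g5    g6
#> 0.211 0.201 0.273 0.131 0.221 0.000

pen  <- gis_penalty(gis)                    # wGIS in [0.5, 1]
round(range(pen), 3)
#> [1] 0.759 1.000

expr <- sim_expression(120, 50, cbind(c(3, 7, 12), c(2, -1.5, 1)), seed = 3)
fit  <- wlasso(expr$x, expr$y, lambda = 0.05, penalty.factor = pen,
               family = "binomial")
fit
#> Weighted-LASSO binomial model (lambda = 0.05, scale = mean)
#>   13 of 50 features selected; intercept = 0.103
#>   converged: TRUE (6 iterations)
```

The scores mean what they read as: `g6` has no annotations (`GIS = 0`, full
penalty 1), `g3` has the richest closure of this draw and so the lowest
penalty, and the fit selects 13 genes including the three truly informative
ones (`g3`, `g7`, `g12`), with the better-annotated ones shrunk less.
Tuning the regularization and the penalty shape jointly:

```r
cv <- cv_wlasso(expr$x, expr$y, family = "binomial", gis = gis,
                shape = c(0.5, 1, 2), nfolds = 5, seed = 4)
cv
#> Cross-validated weighted LASSO (binomial, metric = accuracy)
#>   grid: 30 (lambda, shape) pairs, 5 folds
#>   best lambda = 0.02368, shape = 0.5; accuracy = 0.7833
#>   refit selects 23 features
```

Real data enter through `read_obo()` (OBO 1.2/1.4), `read_annotations()`
(GAF 2.x or two-column TSV) and `read_expression()` (CSV/TSV with a label
column); `gislasso_pipeline()` chains everything and writes TSV/JSON
artifacts, and `inst/scripts/gislasso.R` exposes the same steps as shell
subcommands. The sensitivity harnesses `run_multicollinearity()` (10 noisy
copies of a feature under five penalty scenarios) and
`run_predictive_power()` (penalty overrides emulating incomplete or wrong
priors) reproduce the simulation protocols on synthetic data; see the
methods vignette (`vignettes/gis-weighted-lasso.Rmd`) for the model,
conventions and design decisions.

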