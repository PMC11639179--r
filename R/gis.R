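# Gene Information Score and its transform into feature-specific penalties.

#' Gene Information Score
#'
#' Summarizes the prior knowledge available for each gene as the arithmetic
#' mean of the positive entries of its row in the weighted annotation matrix
#' `W` — i.e. the mean structure-based information content of all terms in
#' the gene's unfolded annotation list, pooled over ontologies:
#' \deqn{GIS(g) = \frac{\sum_{m:\,W_{g,t_m}>0} W_{g,t_m}}
#'                    {\sum_{m:\,W_{g,t_m}>0} 1}.}
#' A gene with no positive entries (no annotations, or annotations only to
#' zero-information terms) scores 0 by convention: no prior biological
#' information exists for it. Scores lie in `[0, 1]`.
#'
#' @param matrices an `"annotation_matrices"` object (see
#'   [annotation_matrices()]).
#' @return named numeric vector of scores in `[0, 1]`, one per gene, in the
#'   matrices' gene order.
#' @examples
#' ont <- sim_ontology(40, seed = 1)
#' ann <- sim_annotations(paste0("g", 1:10), ont, seed = 2)
#' am <- annotation_matrices(ann, ont)
#' gene_information_score(am)
#' @export
gene_information_score <- function(matrices) {
  stopifnot(inherits(matrices, "annotation_matrices"))
  W <- matrices$W
  pos <- W > 0
  n_pos <- Matrix::rowSums(pos)
  total <- Matrix::rowSums(W)
  gis <- ifelse(n_pos > 0, total / pmax(n_pos, 1), 0)
  stats::setNames(as.numeric(gis), matrices$genes)
}

#' Transform Gene Information Scores into L1 penalty factors
#'
#' Maps each gene's relevance score into a multiplicative penalty for the
#' weighted LASSO via the one-parameter family
#' \deqn{w(g) = \frac{1}{1 + shape \cdot GIS(g)},}
#' so better-annotated genes are penalized less. With the default
#' `shape = 1` this is the canonical transform: scores in `[0, 1]` map onto
#' penalties in `[0.5, 1]`, with `w = 1` for genes without prior knowledge
#' and `w = 0.5` at the maximal score. `shape = 0` gives unit penalties for
#' every gene, i.e. the standard (unweighted) LASSO; larger shapes push
#' annotated genes' penalties further below 1. The map is strictly
#' decreasing in the score whenever `shape > 0`.
#'
#' @param gis numeric vector of Gene Information Scores in `[0, 1]` (e.g.
#'   from [gene_information_score()]).
#' @param shape non-negative scale parameter of the transform; default 1.
#' @return numeric vector of penalty factors, named like `gis`.
#' @examples
#' gis_penalty(c(none = 0, half = 0.5, full = 1))
#' @export
gis_penalty <- function(gis, shape = 1) {
  if (!is.numeric(shape) || length(shape) != 1L || is.na(shape) || shape < 0)
    stop("'shape' must be a single non-negative number", call. = FALSE)
  if (any(gis < 0 | gis > 1, na.rm = TRUE))
    stop("Gene Information Scores must lie in [0, 1]", call. = FALSE)
  1 / (1 + shape * gis)
}

#' Per-gene score/penalty table
#'
#' @param matrices an `"annotation_matrices"` object.
#' @param shape penalty-transform shape parameter (see [gis_penalty()]).
#' @return data frame with columns `gene_id`, `n_annotated_terms` (positive
#'   entries of the gene's row in `W`), `gis` and `wgis`.
#' @export
gis_table <- function(matrices, shape = 1) {
  stopifnot(inherits(matrices, "annotation_matrices"))
  gis <- gene_information_score(matrices)
  data.frame(gene_id = matrices$genes,
             n_annotated_terms = as.integer(Matrix::rowSums(matrices$W > 0)),
             gis = as.numeric(gis),
             wgis = as.numeric(gis_penalty(gis, shape)),
             row.names = NULL, stringsAsFactors = FALSE)
}
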