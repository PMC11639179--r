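# Expression-matrix I/O and the end-to-end pipeline
# (ontology -> annotations -> GIS -> penalties -> fit -> report).

#' Read an expression matrix with a label column
#'
#' Reads a CSV/TSV file whose first column holds sample identifiers, one
#' designated column holds the response (class label or numeric outcome),
#' and all remaining columns hold numeric per-gene values. The delimiter is
#' chosen by extension (`.csv` vs anything else), falling back to a sniff of
#' the header line.
#'
#' @param path path to the file.
#' @param label_column name of the response column.
#' @return an `"expr_dataset"`: list with `x` (numeric matrix, samples x
#'   genes), `y` (numeric, or factor for non-numeric labels) and `family`
#'   (`"gaussian"` for numeric labels, `"binomial"` otherwise).
#' @export
read_expression <- function(path, label_column) {
  if (!file.exists(path)) stop("cannot read expression file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else
    if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  if (ncol(df) < 3L) stop("expected sample-id column, label column and at ",
                          "least one gene column", call. = FALSE)
  gene_names <- names(df)[-1L]
  gene_names <- gene_names[gene_names != label_column]
  dup <- unique(gene_names[duplicated(gene_names)])
  if (length(dup))
    stop("duplicated gene column(s): ", paste(dup, collapse = ", "), call. = FALSE)
  sample_ids <- as.character(df[[1L]])
  df <- df[-1L]
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found", call. = FALSE)
  y_raw <- df[[label_column]]
  df <- df[names(df) != label_column]
  bad <- character(0)
  for (g in names(df)) {
    v <- suppressWarnings(as.numeric(df[[g]]))
    nonnum <- which(is.na(v) & !is.na(df[[g]]))
    if (length(nonnum))
      bad <- c(bad, paste0(g, "[", sample_ids[nonnum], "]=", df[[g]][nonnum]))
    df[[g]] <- v
  }
  if (length(bad))
    stop("non-numeric expression cell(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  x <- as.matrix(df)
  rownames(x) <- sample_ids
  numeric_label <- !anyNA(suppressWarnings(as.numeric(y_raw)))
  y <- if (numeric_label) as.numeric(y_raw) else factor(y_raw)
  structure(list(x = x, y = y,
                 family = if (numeric_label) "gaussian" else "binomial",
                 generator = NULL),
            class = "expr_dataset")
}

#' Read penalties back from a written GIS table
#'
#' @param path a TSV written by [gislasso_pipeline()] (or
#'   [write.table()] of [gis_table()]).
#' @return named numeric vector of `wgis` penalty factors.
#' @export
read_gis_penalties <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "wgis") %in% names(df)))
    stop("expected columns 'gene_id' and 'wgis' in ", path, call. = FALSE)
  stats::setNames(as.numeric(df$wgis), df$gene_id)
}

.write_tsv <- function(df, path, digits = 17) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.*g", digits, df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full knowledge-guided feature-selection pipeline
#'
#' Chains the package end to end: parse the ontologies, read and unfold the
#' annotations, build the annotation matrices, score every gene
#' ([gene_information_score()]), transform scores into penalties
#' ([gis_penalty()]), fit the weighted-LASSO model on the expression data
#' (with cross-validated `lambda`/`shape` selection when grids are given,
#' and one-vs-rest decomposition for multiclass labels), and write all
#' artifacts into `out_dir`. Genes present in the expression data but
#' absent from the annotations get a score of 0 and hence the maximal
#' penalty 1. Reruns with the same inputs and seed produce identical
#' numeric outputs.
#'
#' @param obo character vector of OBO file paths.
#' @param annotations character vector of annotation file paths (GAF or
#'   two-column TSV; see [read_annotations()]).
#' @param expression path to the expression matrix (see
#'   [read_expression()]).
#' @param label_column response column name in the expression file.
#' @param out_dir output directory (created if needed).
#' @param relationships relationship filter for the ontology DAGs.
#' @param lambda numeric vector: a single value fits directly, a grid
#'   triggers cross-validation.
#' @param shape penalty-transform shape (scalar, or grid for CV).
#' @param nfolds CV folds.
#' @param seed integer seed recorded in the report and used for fold
#'   assignment.
#' @param lambda.scale lambda convention (see [wlasso()]).
#' @param min_overlap warn if the fraction of expression genes covered by
#'   the annotations falls below this; zero overlap is an error.
#' @return invisibly, a list with the fitted model, the GIS table and the
#'   paths written.
#' @export
gislasso_pipeline <- function(obo, annotations, expression, label_column,
                              out_dir, relationships = c("is_a", "part_of"),
                              lambda = 0.1, shape = 1, nfolds = 5, seed = 1,
                              lambda.scale = c("mean", "sum"),
                              min_overlap = 0.5) {
  lambda.scale <- match.arg(lambda.scale)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  onts <- lapply(obo, read_obo, relationships = relationships)
  for (o in onts) {
    p <- file.path(out_dir, paste0("term_stats_", o$id, ".tsv"))
    .write_tsv(ontology_stats(o), p)
    paths <- c(paths, p)
  }

  asets <- lapply(annotations, read_annotations)
  genes_ann <- unique(unlist(lapply(asets, `[[`, "genes")))
  direct <- lapply(stats::setNames(genes_ann, genes_ann), function(g)
    unique(unlist(lapply(asets, function(a) a$direct[[g]]), use.names = FALSE)))
  aset <- new_annotation_set(genes_ann, direct)

  expr <- read_expression(expression, label_column)
  genes_expr <- colnames(expr$x)
  overlap <- mean(genes_expr %in% genes_ann)
  if (overlap == 0)
    stop("no overlap between expression genes and annotated genes", call. = FALSE)
  if (overlap < min_overlap)
    warning(sprintf("only %.1f%% of expression genes have annotations", 100 * overlap))

  am <- annotation_matrices(aset, onts)
  gt <- gis_table(am, shape = shape[[1L]])
  gis <- stats::setNames(gt$gis, gt$gene_id)[genes_expr]
  gis[is.na(gis)] <- 0
  names(gis) <- genes_expr
  gt_expr <- data.frame(gene_id = genes_expr,
                        n_annotated_terms = gt$n_annotated_terms[match(genes_expr, gt$gene_id)],
                        gis = as.numeric(gis), stringsAsFactors = FALSE)
  gt_expr$n_annotated_terms[is.na(gt_expr$n_annotated_terms)] <- 0L
  gt_expr$wgis <- as.numeric(gis_penalty(gis, shape[[1L]]))
  p <- file.path(out_dir, "gis.tsv")
  .write_tsv(gt_expr, p)
  paths <- c(paths, p)

  multiclass <- is.factor(expr$y) && nlevels(expr$y) > 2L
  cv <- NULL
  if (!multiclass && (length(lambda) > 1L || length(shape) > 1L)) {
    yfit <- if (is.factor(expr$y)) as.numeric(expr$y) - 1 else expr$y
    cv <- cv_wlasso(expr$x, yfit, family = expr$family, lambda = lambda,
                    gis = gis, shape = shape, nfolds = nfolds, seed = seed,
                    lambda.scale = lambda.scale)
    p <- file.path(out_dir, "cv_table.tsv")
    .write_tsv(cv$table, p)
    paths <- c(paths, p)
    fit <- cv$fit
    best_lambda <- cv$best_lambda
    best_shape <- if (is.na(cv$best_shape)) shape[[1L]] else cv$best_shape
  } else {
    best_lambda <- lambda[[1L]]
    best_shape <- shape[[1L]]
    pf <- gis_penalty(gis, best_shape)
    fit <- if (multiclass)
      wlasso_ovr(expr$x, expr$y, lambda = best_lambda, penalty.factor = pf,
                 lambda.scale = lambda.scale)
    else {
      yfit <- if (is.factor(expr$y)) as.numeric(expr$y) - 1 else expr$y
      wlasso(expr$x, yfit, lambda = best_lambda, penalty.factor = pf,
             family = expr$family, lambda.scale = lambda.scale)
    }
  }

  coefs <- if (inherits(fit, "wlasso_ovr")) {
    do.call(rbind, lapply(fit$classes, function(cl) {
      m <- fit$models[[cl]]
      data.frame(gene_id = names(m$beta), class = cl, beta = as.numeric(m$beta),
                 selected = names(m$beta) %in% m$selected,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene_id = names(fit$beta), class = "binary",
               beta = as.numeric(fit$beta),
               selected = names(fit$beta) %in% fit$selected,
               stringsAsFactors = FALSE)
  }
  p <- file.path(out_dir, "coefficients.tsv")
  .write_tsv(coefs, p)
  paths <- c(paths, p)

  report <- list(
    seed = seed, lambda = best_lambda, shape = best_shape,
    lambda_grid = lambda, shape_grid = shape,
    lambda_scale = lambda.scale, family = expr$family,
    multiclass = if (multiclass) "one-vs-rest" else "none",
    conventions = list(
      depth = "longest path from any root, roots at depth 0",
      relationship_filter = relationships,
      log_base = "natural (ratio is base-invariant)",
      standardize = TRUE,
      loss_scale = "mean (1/n) negative log-likelihood"),
    n_samples = nrow(expr$x), n_genes = ncol(expr$x),
    annotation_overlap = overlap,
    n_selected = if (inherits(fit, "wlasso_ovr"))
      lengths(fit$selected) else length(fit$selected),
    package_version = as.character(utils::packageVersion("gislasso")))
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, p)

  invisible(list(fit = fit, cv = cv, gis_table = gt_expr, paths = paths))
}
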