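# Cross-validated (lambda, shape) selection and one-vs-rest multiclass.

# smallest lambda that zeroes every penalized coefficient at the null model
.lambda_max <- function(x, y, family, penalty.factor) {
  x <- as.matrix(x)
  n <- nrow(x)
  center <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2L, center)^2))
  keep <- scl > .Machine$double.eps^0.5
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2L, center[keep]), 2L, scl[keep], "/")
  if (family == "binomial") y <- .check_binomial_y(y)
  g <- abs(drop(crossprod(xs, y - mean(y)))) / n
  w <- penalty.factor[keep]
  pos <- w > 0
  if (!any(pos)) return(Inf)
  max(g[pos] / w[pos])
}

.make_folds <- function(y, nfolds, stratify) {
  n <- length(y)
  foldid <- integer(n)
  if (stratify) {
    # rotate the fold counter across classes so overall fold sizes stay
    # within one of each other while each class is split as evenly as possible
    counter <- 0L
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      foldid[idx] <- (counter + seq_along(idx) - 1L) %% nfolds + 1L
      counter <- counter + length(idx)
    }
  } else {
    foldid[sample(n)] <- rep_len(seq_len(nfolds), n)
  }
  foldid
}

#' Cross-validated selection of lambda (and penalty shape)
#'
#' Grid-searches the regularization strength `lambda` and, when a vector of
#' Gene Information Scores is supplied, the shape parameter of the penalty
#' transform ([gis_penalty()]) jointly by k-fold cross-validation. Folds are
#' stratified by class for the binomial family. The metric is classification
#' accuracy (binomial; class threshold 0.5) or mean squared error
#' (gaussian). Ties are broken toward the larger `lambda` (the sparser
#' model) and then the smaller shape.
#'
#' @inheritParams wlasso
#' @param lambda numeric vector of candidate strengths; if `NULL`, a
#'   log-spaced grid of `nlambda` values below the null-model threshold is
#'   used.
#' @param gis optional named vector of Gene Information Scores aligned with
#'   `colnames(x)`; penalties for each candidate `shape` are
#'   `gis_penalty(gis, shape)`. When `NULL`, `penalty.factor` is used as-is
#'   and the shape grid collapses to a single entry.
#' @param shape numeric vector of candidate shapes (default 1).
#' @param penalty.factor fixed penalties used when `gis` is `NULL`.
#' @param nfolds number of folds (>= 2).
#' @param nlambda grid size when `lambda` is `NULL`.
#' @param seed optional integer seed for the fold assignment.
#' @param ... passed on to [wlasso()].
#' @return an object of class `"cv_wlasso"`: list with the CV `table`
#'   (`lambda`, `shape`, metric mean and sd), `best_lambda`, `best_shape`,
#'   `metric` name, the `fit` refitted on the full data at the best pair,
#'   and the fold assignment.
#' @export
cv_wlasso <- function(x, y, family = c("gaussian", "binomial"), lambda = NULL,
                      gis = NULL, shape = 1,
                      penalty.factor = rep(1, ncol(x)), nfolds = 5,
                      nlambda = 10, seed = NULL,
                      lambda.scale = c("mean", "sum"), ...) {
  family <- match.arg(family)
  lambda.scale <- match.arg(lambda.scale)
  x <- as.matrix(x)
  if (nfolds < 2L) stop("'nfolds' must be at least 2", call. = FALSE)
  if (family == "binomial") y <- .check_binomial_y(y) else y <- as.numeric(y)
  if (!is.null(seed)) {
    old_seed <- .save_rng()
    on.exit(.restore_rng(old_seed), add = TRUE)
    set.seed(seed)
  }

  pf_for <- function(s) {
    if (is.null(gis)) penalty.factor else {
      g <- gis[colnames(x)]
      g[is.na(g)] <- 0
      gis_penalty(g, s)
    }
  }
  if (is.null(gis)) shape <- shape[1L]
  if (is.null(lambda)) {
    lmax <- .lambda_max(x, y, family, pf_for(min(shape)))
    if (lambda.scale == "sum") lmax <- lmax * nrow(x)
    lambda <- exp(seq(log(lmax * 0.999), log(lmax * 0.01), length.out = nlambda))
  }
  if (!length(lambda) || !length(shape)) stop("empty grid", call. = FALSE)

  foldid <- .make_folds(y, nfolds, stratify = family == "binomial")
  if (family == "binomial") {
    for (attempt in 1:10) {
      single <- vapply(seq_len(nfolds), function(k)
        length(unique(y[foldid != k])) < 2L, logical(1))
      if (!any(single)) break
      warning("fold with a single training class; refolding")
      foldid <- .make_folds(y, nfolds, stratify = TRUE)
    }
  }

  grid <- expand.grid(lambda = lambda, shape = shape, KEEP.OUT.ATTRS = FALSE)
  metric <- matrix(NA_real_, nrow(grid), nfolds)
  for (k in seq_len(nfolds)) {
    tr <- foldid != k
    for (r in seq_len(nrow(grid))) {
      fit <- wlasso(x[tr, , drop = FALSE], y[tr], lambda = grid$lambda[r],
                    penalty.factor = pf_for(grid$shape[r]), family = family,
                    lambda.scale = lambda.scale, ...)
      if (family == "binomial") {
        pred <- predict(fit, x[!tr, , drop = FALSE], type = "class")
        metric[r, k] <- mean(pred == y[!tr])
      } else {
        pred <- predict(fit, x[!tr, , drop = FALSE], type = "response")
        metric[r, k] <- mean((pred - y[!tr])^2)
      }
    }
  }
  tab <- data.frame(lambda = grid$lambda, shape = grid$shape,
                    metric_mean = rowMeans(metric),
                    metric_sd = apply(metric, 1L, stats::sd))
  metric_name <- if (family == "binomial") "accuracy" else "mse"
  ord <- if (family == "binomial")
    order(-tab$metric_mean, -tab$lambda, tab$shape)
  else order(tab$metric_mean, -tab$lambda, tab$shape)
  best <- tab[ord[1L], ]
  fit <- wlasso(x, y, lambda = best$lambda, penalty.factor = pf_for(best$shape),
                family = family, lambda.scale = lambda.scale, ...)
  structure(list(table = tab, best_lambda = best$lambda,
                 best_shape = if (is.null(gis)) NA_real_ else best$shape,
                 metric = metric_name, fit = fit, foldid = foldid,
                 family = family, call = match.call()),
            class = "cv_wlasso")
}

#' @export
print.cv_wlasso <- function(x, ...) {
  cat("Cross-validated weighted LASSO (", x$family, ", metric = ", x$metric,
      ")\n", sep = "")
  cat("  grid: ", nrow(x$table), " (lambda, shape) pairs, ",
      max(x$foldid), " folds\n", sep = "")
  cat("  best lambda = ", format(signif(x$best_lambda, 4)),
      if (!is.na(x$best_shape)) paste0(", shape = ", format(x$best_shape)),
      "; ", x$metric, " = ",
      format(signif(x$table$metric_mean[which(x$table$lambda == x$best_lambda &
        (is.na(x$best_shape) | x$table$shape == x$best_shape))[1L]], 4)),
      "\n", sep = "")
  cat("  refit selects ", length(x$fit$selected), " features\n", sep = "")
  invisible(x)
}

#' One-vs-rest multiclass weighted LASSO
#'
#' Fits one binary weighted-LASSO logistic model per class (class vs rest)
#' and predicts by the maximal linear score. The per-class selected gene
#' sets are exposed for downstream set analyses.
#'
#' @inheritParams wlasso
#' @param y factor (or coercible) with at least 2 classes, each with at
#'   least 2 samples.
#' @param ... passed on to [wlasso()] (family is fixed to binomial).
#' @return an object of class `"wlasso_ovr"`: list of per-class `"wlasso"`
#'   fits plus `classes` and `selected` (named list of per-class selected
#'   features).
#' @export
wlasso_ovr <- function(x, y, lambda, penalty.factor = rep(1, ncol(x)), ...) {
  y <- factor(y)
  counts <- table(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(counts < 2L))
    stop("every class needs at least 2 samples (violated by: ",
         paste(names(counts)[counts < 2L], collapse = ", "), ")", call. = FALSE)
  models <- lapply(levels(y), function(cl)
    wlasso(x, as.numeric(y == cl), lambda = lambda,
           penalty.factor = penalty.factor, family = "binomial", ...))
  names(models) <- levels(y)
  structure(list(models = models, classes = levels(y), lambda = lambda,
                 selected = lapply(models, `[[`, "selected"),
                 call = match.call()),
            class = "wlasso_ovr")
}

#' @export
print.wlasso_ovr <- function(x, ...) {
  cat("One-vs-rest weighted-LASSO logistic model, ", length(x$classes),
      " classes (lambda = ", format(x$lambda), ")\n", sep = "")
  for (cl in x$classes)
    cat("  ", cl, ": ", length(x$selected[[cl]]), " features selected\n", sep = "")
  invisible(x)
}

#' @param object a `"wlasso_ovr"` fit.
#' @param newx matrix of new observations.
#' @param type `"class"` (default) or `"score"` (matrix of per-class linear
#'   scores).
#' @param ... unused.
#' @rdname wlasso_ovr
#' @export
predict.wlasso_ovr <- function(object, newx, type = c("class", "score"), ...) {
  type <- match.arg(type)
  scores <- vapply(object$models, function(m) predict(m, newx, type = "link"),
                   numeric(nrow(as.matrix(newx))))
  scores <- matrix(scores, ncol = length(object$models),
                   dimnames = list(NULL, object$classes))
  if (type == "score") return(scores)
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

#' Union, intersection and frequency of selected feature sets
#'
#' Summarizes the features selected by several fitted models (e.g. across
#' training-set permutations): their union, their intersection, and how
#' often each feature was selected.
#'
#' @param models a list of `"wlasso"` fits, or a list of character vectors
#'   of selected feature names.
#' @return list with `union`, `intersection` and `frequency` (named integer
#'   vector over the union).
#' @export
selection_sets <- function(models) {
  if (!length(models)) stop("'models' must be non-empty", call. = FALSE)
  sets <- lapply(models, function(m)
    if (inherits(m, "wlasso")) m$selected else as.character(m))
  u <- Reduce(union, sets)
  i <- Reduce(intersect, sets)
  freq <- vapply(u, function(f) sum(vapply(sets, function(s) f %in% s,
                                           logical(1))), integer(1))
  list(union = u, intersection = i,
       frequency = stats::setNames(as.integer(freq), u))
}
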