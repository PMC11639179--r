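# Synthetic ontologies, annotations and expression data, plus the
# multicollinearity and predictive-power sensitivity harnesses.

#' Generate a random DAG ontology
#'
#' Builds a single-root random ontology: a root-to-leaf backbone chain of
#' `depth_target` edges guarantees the requested height, every further term
#' attaches to a random existing parent (preferring parents with fewer than
#' `max_children` children), and with probability `p_extra_parent` a term
#' receives a second parent, producing the multi-parent diamonds typical of
#' real ontologies. Edges always point from newer to older terms, so the
#' graph is acyclic by construction and every term is reachable from the
#' root. Deterministic for a fixed seed.
#'
#' @param n_terms number of terms (>= 2).
#' @param max_children soft cap on children per term.
#' @param depth_target guaranteed minimum height of the DAG (must be
#'   `<= n_terms - 1`).
#' @param p_extra_parent probability that a non-backbone term gets a second
#'   parent.
#' @param seed optional integer seed.
#' @param id ontology label.
#' @return an `"ontology"` object (see [read_obo()]).
#' @export
sim_ontology <- function(n_terms, max_children = 3, depth_target = 5,
                         p_extra_parent = 0.1, seed = NULL, id = "simont") {
  if (n_terms < 2L) stop("'n_terms' must be at least 2", call. = FALSE)
  depth_target <- min(depth_target, n_terms - 1L)
  if (depth_target < 1L || max_children < 1L)
    stop("infeasible shape parameters", call. = FALSE)
  if (!is.null(seed)) {
    old_seed <- .save_rng()
    on.exit(.restore_rng(old_seed), add = TRUE)
    set.seed(seed)
  }
  ids <- sprintf("%s:%04d", toupper(substr(id, 1, 2)), seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  n_children <- stats::setNames(integer(n_terms), ids)
  # backbone chain fixes the height
  for (i in seq_len(depth_target)) {
    parents[[ids[i + 1L]]] <- ids[i]
    n_children[[ids[i]]] <- 1L
  }
  if (n_terms > depth_target + 1L) {
    for (i in (depth_target + 2L):n_terms) {
      pool <- ids[seq_len(i - 1L)]
      open <- pool[n_children[pool] < max_children]
      p1 <- if (length(open)) sample(open, 1L) else sample(pool, 1L)
      ps <- p1
      if (i > 2L && stats::runif(1) < p_extra_parent) {
        p2 <- sample(setdiff(pool, p1), 1L)
        ps <- c(ps, p2)
      }
      parents[[ids[i]]] <- ps
      n_children[ps] <- n_children[ps] + 1L
    }
  }
  .new_ontology(id, parents, stats::setNames(ids, ids))
}

#' Generate random most-specific annotations
#'
#' Assigns each annotated gene a `1 + Poisson(mean_terms_per_gene - 1)`
#' number of most-specific terms, drawn without replacement with probability
#' proportional to `(depth + 1)^2` (biased toward deeper, more specific
#' terms); sampled terms that are ancestors of other sampled terms are
#' pruned so the direct annotations are most-specific. A
#' `frac_unannotated` share of genes (rounded) receives no annotations, so
#' genes with a zero Gene Information Score exist by construction.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param ontology an `"ontology"` object.
#' @param mean_terms_per_gene expected number of direct terms per annotated
#'   gene (> 0).
#' @param frac_unannotated fraction of genes left unannotated, in `[0, 1)`.
#' @param seed optional integer seed.
#' @return an `"annotation_set"` (direct annotations only).
#' @export
sim_annotations <- function(gene_ids, ontology, mean_terms_per_gene = 2,
                            frac_unannotated = 0.1, seed = NULL) {
  stopifnot(inherits(ontology, "ontology"))
  if (mean_terms_per_gene <= 0) stop("'mean_terms_per_gene' must be > 0", call. = FALSE)
  if (frac_unannotated < 0 || frac_unannotated >= 1)
    stop("'frac_unannotated' must be in [0, 1)", call. = FALSE)
  if (!is.null(seed)) {
    old_seed <- .save_rng()
    on.exit(.restore_rng(old_seed), add = TRUE)
    set.seed(seed)
  }
  q <- length(gene_ids)
  n_un <- round(frac_unannotated * q)
  unann <- if (n_un > 0L) sample(gene_ids, n_un) else character(0)
  prob <- (ontology$depth + 1)^2
  anc <- .ancestor_sets(ontology$parents)
  direct <- lapply(stats::setNames(gene_ids, gene_ids), function(g) {
    if (g %in% unann) return(character(0))
    k <- 1L + stats::rpois(1L, max(mean_terms_per_gene - 1, 0))
    k <- min(k, ontology$total_terms)
    terms <- sample(ontology$terms, k, prob = prob)
    # keep only most-specific: drop terms that are ancestors of another
    ancestors_of_others <- unique(unlist(anc[terms], use.names = FALSE))
    keep <- setdiff(terms, ancestors_of_others)
    if (!length(keep)) terms else keep
  })
  new_annotation_set(gene_ids, direct)
}

#' Generate a synthetic expression dataset
#'
#' Draws an `n_samples x n_genes` matrix of independent standard-normal
#' features (as a stand-in for standardized expression profiles) and a
#' response generated from the designated informative features: binary
#' labels from a zero-intercept logistic model (so the two classes are
#' balanced in expectation) or a gaussian response with unit noise.
#'
#' @param n_samples,n_genes dataset dimensions.
#' @param informative either `NULL` (pure noise) or a two-column object
#'   (`index`, `effect`) — e.g. `cbind(index = c(1, 5), effect = c(2, -1))`
#'   — giving the true nonzero effect sizes.
#' @param family `"binomial"` (binary labels) or `"gaussian"`.
#' @param seed optional integer seed.
#' @return an object of class `"expr_dataset"`: list with `x` (named
#'   matrix), `y`, `family`, `informative` and the generator parameters
#'   (used by [run_predictive_power()] to redraw replicate datasets).
#' @export
sim_expression <- function(n_samples, n_genes, informative = NULL,
                           family = c("binomial", "gaussian"), seed = NULL) {
  family <- match.arg(family)
  if (!is.null(informative)) {
    informative <- as.matrix(informative)
    if (ncol(informative) != 2L) stop("'informative' needs columns (index, effect)", call. = FALSE)
    if (any(informative[, 1L] < 1 | informative[, 1L] > n_genes))
      stop("informative indices out of range", call. = FALSE)
  }
  if (!is.null(seed)) {
    old_seed <- .save_rng()
    on.exit(.restore_rng(old_seed), add = TRUE)
    set.seed(seed)
  }
  x <- matrix(stats::rnorm(n_samples * n_genes), n_samples, n_genes,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("g", seq_len(n_genes))))
  eta <- if (is.null(informative)) rep(0, n_samples) else
    drop(x[, informative[, 1L], drop = FALSE] %*% informative[, 2L])
  y <- if (family == "binomial") stats::rbinom(n_samples, 1L, stats::plogis(eta))
       else eta + stats::rnorm(n_samples)
  structure(list(x = x, y = y, family = family, informative = informative,
                 generator = list(n_samples = n_samples, n_genes = n_genes,
                                  informative = informative, family = family,
                                  seed = seed)),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("Expression dataset: ", nrow(x$x), " samples x ", ncol(x$x),
      " features (", x$family, " response)\n", sep = "")
  if (x$family == "binomial")
    cat("  class balance: ", sum(x$y == 1), " / ", sum(x$y == 0), "\n", sep = "")
  invisible(x)
}

#' Fisher's score of each feature for a binary class label
#'
#' Ratio of between-class to within-class variability per feature:
#' \deqn{F_j = \frac{\sum_c n_c (\mu_{c,j} - \mu_j)^2}
#'                  {\sum_c n_c \sigma^2_{c,j}}}
#' with class sizes `n_c`, class means, overall mean, and
#' maximum-likelihood class variances. Features with zero pooled
#' within-class variance but distinct class means are reported as `Inf`
#' with a warning.
#'
#' @param x feature matrix (samples in rows).
#' @param y binary class labels (two distinct values, each with >= 2
#'   samples).
#' @return named numeric vector of scores, one per column of `x`.
#' @export
fisher_score <- function(x, y) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("'y' must have exactly two classes", call. = FALSE)
  if (any(table(y) < 2L)) stop("each class needs at least 2 samples", call. = FALSE)
  mu <- colMeans(x)
  num <- 0; den <- 0
  for (cl in levels(y)) {
    xi <- x[y == cl, , drop = FALSE]
    nc <- nrow(xi)
    mc <- colMeans(xi)
    vc <- colMeans(sweep(xi, 2L, mc)^2)
    num <- num + nc * (mc - mu)^2
    den <- den + nc * vc
  }
  score <- ifelse(den > 0, num / ifelse(den > 0, den, 1),
                  ifelse(num > 0, Inf, 0))
  if (any(is.infinite(score)))
    warning("zero within-class variance for ",
            sum(is.infinite(score)), " feature(s); score reported as Inf")
  stats::setNames(as.numeric(score), colnames(x))
}

#' Build a low-correlation controlled dataset
#'
#' Emulates the construction of a controlled benchmark: first picks
#' `n_seed_features` seed features spanning distinct Fisher's-score strata
#' (quantile bins of the score) with pairwise Pearson correlation below
#' `corr_cap_seed`, then randomly fills the dataset with `n_fill` further
#' features whose correlation is below `corr_cap_seed` with every seed
#' feature and below `corr_cap_fill` with every other fill feature.
#' Deterministic per seed.
#'
#' @param data an `"expr_dataset"` with a binary response.
#' @param n_seed_features number of graded-predictive-value seed features.
#' @param corr_cap_seed correlation cap involving seed features.
#' @param n_fill number of additional features.
#' @param corr_cap_fill correlation cap among fill features.
#' @param seed optional integer seed.
#' @return an `"expr_dataset"` restricted to the selected columns (seed
#'   features first), with elements `seed_features` and `fisher` added.
#' @export
controlled_dataset <- function(data, n_seed_features = 5, corr_cap_seed = 0.5,
                               n_fill = 995, corr_cap_fill = 0.70,
                               seed = NULL) {
  stopifnot(inherits(data, "expr_dataset"))
  if (!is.null(seed)) {
    old_seed <- .save_rng()
    on.exit(.restore_rng(old_seed), add = TRUE)
    set.seed(seed)
  }
  x <- data$x
  fs <- fisher_score(x, data$y)
  strata <- cut(rank(fs, ties.method = "first"),
                breaks = n_seed_features, labels = FALSE)
  seeds <- character(0)
  for (s in rev(seq_len(n_seed_features))) {   # high-score strata first
    # within a stratum, prefer the most discriminative admissible feature so
    # the seeds span graded predictive values down from the strongest
    cands <- names(fs)[strata == s]
    cands <- cands[order(-fs[cands])]
    ok <- FALSE
    for (cand in cands) {
      if (!length(seeds) ||
          all(abs(stats::cor(x[, cand], x[, seeds])) < corr_cap_seed)) {
        seeds <- c(seeds, cand); ok <- TRUE; break
      }
    }
    if (!ok)
      stop("could not find a seed feature in stratum ", s,
           " under the correlation cap", call. = FALSE)
  }
  fill <- character(0)
  cands <- sample(setdiff(colnames(x), seeds))
  for (cand in cands) {
    if (length(fill) >= n_fill) break
    r_seed <- abs(stats::cor(x[, cand], x[, seeds]))
    if (any(r_seed >= corr_cap_seed)) next
    if (length(fill) &&
        any(abs(stats::cor(x[, cand], x[, fill])) >= corr_cap_fill)) next
    fill <- c(fill, cand)
  }
  if (length(fill) < n_fill)
    stop("correlation caps unsatisfiable: only ", length(fill), " of ",
         n_fill, " fill features found (", length(cands),
         " candidates examined)", call. = FALSE)
  keep <- c(seeds, fill)
  out <- data
  out$x <- x[, keep, drop = FALSE]
  out$seed_features <- seeds
  out$fisher <- fs[keep]
  out$generator <- NULL   # a column subset is no longer redrawable
  out
}

#' Append noisy copies of a feature
#'
#' Adds `n_copies` columns equal to the designated feature plus independent
#' gaussian noise (`N(0, noise_sd^2)` per entry), the standard construction
#' for studying feature selection under extreme multicollinearity. The
#' original column is relabeled `<gene>_0` and the copies `<gene>_1` ...
#' `<gene>_<n_copies>`.
#'
#' @param data an `"expr_dataset"`.
#' @param gene name of the column to copy.
#' @param n_copies number of copies (default 10).
#' @param noise_sd standard deviation of the added noise (default 0.01).
#' @param seed optional integer seed.
#' @return the dataset with the enlarged matrix and a `block` element
#'   listing the original-plus-copies column labels.
#' @export
add_noisy_copies <- function(data, gene, n_copies = 10, noise_sd = 0.01,
                             seed = NULL) {
  stopifnot(inherits(data, "expr_dataset"))
  if (!gene %in% colnames(data$x)) stop("unknown feature: ", gene, call. = FALSE)
  if (!is.null(seed)) {
    old_seed <- .save_rng()
    on.exit(.restore_rng(old_seed), add = TRUE)
    set.seed(seed)
  }
  orig <- data$x[, gene]
  n <- length(orig)
  copies <- matrix(rep(orig, n_copies) +
                     stats::rnorm(n * n_copies, sd = noise_sd), n, n_copies)
  labels <- paste(gene, seq_len(n_copies), sep = "_")
  colnames(data$x)[colnames(data$x) == gene] <- paste0(gene, "_0")
  colnames(copies) <- labels
  data$x <- cbind(data$x, copies)
  data$block <- c(paste0(gene, "_0"), labels)
  data$generator <- NULL
  data
}

#' Penalty scenarios for the multicollinearity study
#'
#' The five penalty configurations applied to a duplicated-feature block
#' (one original feature plus `n_copies` noisy copies):
#' \describe{
#'   \item{NO_GIS}{no prior knowledge anywhere: original and copies all get
#'     penalty 1 (standard LASSO on the block).}
#'   \item{GIS1}{copies have no prior knowledge (penalty 1); the original
#'     keeps its own penalty.}
#'   \item{GIS2}{copies have little prior knowledge: penalties evenly spaced
#'     in `[0.95, 1.0]`.}
#'   \item{GIS3}{copies evenly spaced in `[original_w, 1.0]`.}
#'   \item{GIS4}{copies evenly spaced over the entire attainable range
#'     `[0.5, 1.0]`.}
#' }
#' All spacings include both endpoints; the smallest penalty goes to copy 1,
#' ascending to the last copy. Except under NO_GIS, the original feature's
#' penalty is left unchanged at `original_w`.
#'
#' @param original_w penalty of the original feature, in `(0, 1]`.
#' @param n_copies number of copies (default 10).
#' @return named list of scenario specifications, each a list with `name`,
#'   `original_w` and the length-`n_copies` vector `copy_w`.
#' @export
gis_scenarios <- function(original_w, n_copies = 10) {
  if (original_w <= 0 || original_w > 1)
    stop("'original_w' must be in (0, 1]", call. = FALSE)
  sc <- list(
    NO_GIS = list(original_w = 1, copy_w = rep(1, n_copies)),
    GIS1 = list(original_w = original_w, copy_w = rep(1, n_copies)),
    GIS2 = list(original_w = original_w,
                copy_w = seq(0.95, 1.0, length.out = n_copies)),
    GIS3 = list(original_w = original_w,
                copy_w = seq(original_w, 1.0, length.out = n_copies)),
    GIS4 = list(original_w = original_w,
                copy_w = seq(0.5, 1.0, length.out = n_copies)))
  for (nm in names(sc)) sc[[nm]]$name <- nm
  sc
}

#' Multicollinearity sensitivity experiment
#'
#' For each repetition, regenerates the noisy copies of the designated
#' feature (the same noise realization is shared across scenarios and
#' lambdas, so comparisons are paired), assigns the block penalties
#' prescribed by each scenario (all other features keep their baseline
#' penalties), fits a binary weighted-LASSO logistic model at each lambda,
#' and records which block members (original or copies) are selected.
#'
#' @param data an `"expr_dataset"` with a binary response (e.g. from
#'   [controlled_dataset()]).
#' @param gene the feature to duplicate.
#' @param scenarios named list from [gis_scenarios()]; default all five with
#'   `original_w` taken from `penalty.factor`.
#' @param lambda vector of regularization strengths.
#' @param reps number of repetitions per (scenario, lambda).
#' @param penalty.factor named baseline penalties for the existing features
#'   (default all 1).
#' @param n_copies,noise_sd copy construction (see [add_noisy_copies()]).
#' @param seed master integer seed; repetition seeds are derived from it.
#' @param lambda.scale lambda convention passed to [wlasso()]; the default
#'   `"sum"` matches platforms that scale the penalty against the summed
#'   loss, under which the conventional lambda values 0.2-1.0 for this
#'   protocol are meaningful.
#' @param max_sweeps sweep budget per fit; near-duplicate columns make the
#'   inner coordinate descent slow, so the harness default is generous.
#' @param ... passed on to [wlasso()].
#' @return an object of class `"multicollinearity_result"`: a data frame of
#'   selection counts with columns `scenario`, `lambda`, `feature`, `count`,
#'   plus attributes `reps`, `gene`, `seed`.
#' @export
run_multicollinearity <- function(data, gene, scenarios = NULL,
                                  lambda = c(0.20, 0.25, 0.50, 1.0),
                                  reps = 100, penalty.factor = NULL,
                                  n_copies = 10, noise_sd = 0.01, seed = 1,
                                  lambda.scale = c("sum", "mean"),
                                  max_sweeps = 1e6, ...) {
  stopifnot(inherits(data, "expr_dataset"))
  lambda.scale <- match.arg(lambda.scale)
  if (data$family != "binomial")
    stop("the multicollinearity protocol uses a binary response", call. = FALSE)
  genes0 <- colnames(data$x)
  if (is.null(penalty.factor)) penalty.factor <- stats::setNames(rep(1, length(genes0)), genes0)
  if (is.null(scenarios)) scenarios <- gis_scenarios(penalty.factor[[gene]], n_copies)
  block <- c(paste0(gene, "_0"), paste(gene, seq_len(n_copies), sep = "_"))

  counts <- list()
  for (nm in names(scenarios)) for (l in lambda)
    counts[[paste(nm, l)]] <- stats::setNames(integer(length(block)), block)
  n_budget <- 0L

  for (rep_i in seq_len(reps)) {
    d <- add_noisy_copies(data, gene, n_copies, noise_sd,
                          seed = .derive_seed(seed, rep_i))
    base_pf <- penalty.factor[genes0]
    names(base_pf) <- colnames(d$x)[seq_along(genes0)]  # gene now gene_0
    for (nm in names(scenarios)) {
      sc <- scenarios[[nm]]
      pf <- c(base_pf, stats::setNames(sc$copy_w, paste(gene, seq_len(n_copies), sep = "_")))
      pf[[paste0(gene, "_0")]] <- sc$original_w
      for (l in lambda) {
        fit <- withCallingHandlers(
          wlasso(d$x, d$y, lambda = l, penalty.factor = pf[colnames(d$x)],
                 family = "binomial", lambda.scale = lambda.scale,
                 max_sweeps = max_sweeps, ...),
          warning = function(w) {
            if (grepl("did not converge", conditionMessage(w))) {
              n_budget <<- n_budget + 1L
              invokeRestart("muffleWarning")
            }
          })
        hit <- intersect(fit$selected, block)
        counts[[paste(nm, l)]][hit] <- counts[[paste(nm, l)]][hit] + 1L
      }
    }
  }

  grid <- expand.grid(feature = block, lambda = lambda,
                      scenario = names(scenarios), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(nm, l, f) counts[[paste(nm, l)]][[f]],
                       grid$scenario, grid$lambda, grid$feature)
  out <- grid[, c("scenario", "lambda", "feature", "count")]
  attr(out, "reps") <- reps
  attr(out, "gene") <- gene
  attr(out, "seed") <- seed
  attr(out, "copy_order") <- "smallest scenario penalty on copy _1, ascending"
  attr(out, "n_budget_stops") <- n_budget
  if (n_budget > 0L)
    message(n_budget, " of ", reps * length(lambda) * length(scenarios),
            " fits stopped at the sweep budget; selected sets are stable ",
            "well before coefficient convergence on duplicated columns")
  class(out) <- c("multicollinearity_result", "data.frame")
  out
}

#' @export
print.multicollinearity_result <- function(x, ...) {
  gene <- attr(x, "gene"); reps <- attr(x, "reps")
  cat("Multicollinearity experiment",
      if (!is.null(gene)) paste0(" on '", gene, "'"),
      if (!is.null(reps)) paste0(": ", reps, " repetitions"), "\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Plot selection counts of a duplicated-feature block
#'
#' @param x a `"multicollinearity_result"`.
#' @param scenario,lambda which experimental arm to draw (defaults: first of
#'   each).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.multicollinearity_result <- function(x, scenario = NULL, lambda = NULL, ...) {
  if (is.null(scenario)) scenario <- x$scenario[[1L]]
  if (is.null(lambda)) lambda <- x$lambda[[1L]]
  sub <- x[x$scenario == scenario & x$lambda == lambda, ]
  graphics::barplot(stats::setNames(sub$count, sub$feature), las = 2,
                    ylab = sprintf("selections / %d reps", attr(x, "reps")),
                    main = sprintf("%s, lambda = %g", scenario, lambda), ...)
  invisible(x)
}

#' Predictive-power sensitivity experiment
#'
#' Studies how perturbing a feature's penalty (emulating incomplete or
#' erroneous prior knowledge) changes its estimated coefficient and its
#' selection frequency. For every override configuration (one feature's
#' penalty forced to a given value, all others at baseline) and every
#' repetition, a replicate dataset is redrawn from the generator parameters
#' stored on the `"expr_dataset"` and a weighted-LASSO logistic or gaussian
#' model is fitted; the feature's coefficient magnitude and selection
#' indicator are recorded.
#'
#' @param data an `"expr_dataset"` produced by [sim_expression()] (replicate
#'   datasets are redrawn from its stored generator parameters when
#'   `reps > 1`).
#' @param overrides data frame with columns `gene` and `w` (one row per
#'   configuration; `w` in `(0, 1]`).
#' @param lambda regularization strength.
#' @param reps repetitions (fresh datasets) per configuration.
#' @param penalty.factor named baseline penalties (default all 1).
#' @param seed master integer seed.
#' @param lambda.scale as in [run_multicollinearity()].
#' @param ... passed on to [wlasso()].
#' @return data frame with one row per override configuration: `gene`, `w`,
#'   `mean_abs_beta`, `selection_freq` over the repetitions.
#' @export
run_predictive_power <- function(data, overrides, lambda = 0.2, reps = 100,
                                 penalty.factor = NULL, seed = 1,
                                 lambda.scale = c("sum", "mean"),
                                 max_sweeps = 1e6, ...) {
  stopifnot(inherits(data, "expr_dataset"))
  lambda.scale <- match.arg(lambda.scale)
  overrides <- as.data.frame(overrides)
  if (!all(c("gene", "w") %in% names(overrides)))
    stop("'overrides' needs columns 'gene' and 'w'", call. = FALSE)
  if (any(overrides$w <= 0 | overrides$w > 1))
    stop("penalty overrides must lie in (0, 1]", call. = FALSE)
  if (reps > 1L && is.null(data$generator))
    stop("replicated runs need a dataset with stored generator parameters ",
         "(see sim_expression)", call. = FALSE)
  genes <- colnames(data$x)
  if (is.null(penalty.factor)) penalty.factor <- stats::setNames(rep(1, length(genes)), genes)

  abs_beta <- matrix(0, nrow(overrides), reps)
  sel <- matrix(0L, nrow(overrides), reps)
  n_budget <- 0L
  for (rep_i in seq_len(reps)) {
    d <- if (reps == 1L) data else {
      g <- data$generator
      sim_expression(g$n_samples, g$n_genes, g$informative, g$family,
                     seed = .derive_seed(seed, rep_i))
    }
    for (r in seq_len(nrow(overrides))) {
      pf <- penalty.factor[genes]
      pf[[overrides$gene[[r]]]] <- overrides$w[[r]]
      fit <- withCallingHandlers(
        wlasso(d$x, d$y, lambda = lambda, penalty.factor = pf,
               family = d$family, lambda.scale = lambda.scale,
               max_sweeps = max_sweeps, ...),
        warning = function(w) {
          if (grepl("did not converge", conditionMessage(w))) {
            n_budget <<- n_budget + 1L
            invokeRestart("muffleWarning")
          }
        })
      abs_beta[r, rep_i] <- abs(fit$beta[[overrides$gene[[r]]]])
      sel[r, rep_i] <- as.integer(overrides$gene[[r]] %in% fit$selected)
    }
  }
  if (n_budget > 0L)
    message(n_budget, " of ", reps * nrow(overrides),
            " fits stopped at the sweep budget")
  data.frame(gene = overrides$gene, w = overrides$w,
             mean_abs_beta = rowMeans(abs_beta),
             selection_freq = rowMeans(sel),
             row.names = NULL, stringsAsFactors = FALSE)
}
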