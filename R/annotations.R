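# Gene -> term annotations: reading, DAG unfolding, and the binary (B) and
# ICstruct-weighted (W) gene x term annotation matrices.

#' Read gene-to-term annotations
#'
#' Reads direct ("most specific") gene annotations either from a GAF 2.x
#' association file (17-column TSV, `!` comment lines, column 2 = gene id,
#' column 4 = qualifier, column 5 = term id; rows whose qualifier contains
#' `NOT` are skipped) or from a plain two-column TSV (`gene_id`, `term_id`).
#' Duplicate gene-term pairs are collapsed; malformed rows are skipped with
#' a warning reporting the count.
#'
#' @param path path to the annotation file.
#' @param format `"auto"` (by extension: `.gaf` vs anything else), `"gaf"`,
#'   or `"tsv"`.
#' @return an object of class `"annotation_set"` with elements `genes`
#'   (ordered gene ids) and `direct` (named list gene -> character vector of
#'   most-specific term ids); the `unfolded` element is `NULL` until
#'   [unfold_annotations()] is applied.
#' @export
read_annotations <- function(path, format = c("auto", "gaf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read annotation file: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.gaf(\\.|$)", basename(path), ignore.case = TRUE)) "gaf" else "tsv"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- 0L
  pairs <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (format == "gaf") {
      if (length(f) < 5L || !nzchar(f[[2L]]) || !nzchar(f[[5L]])) { bad <- bad + 1L; next }
      if (grepl("\\bNOT\\b", f[[4L]])) next
      pairs[[i]] <- c(f[[2L]], f[[5L]])
    } else {
      if (length(f) < 2L || !nzchar(trimws(f[[1L]])) || !nzchar(trimws(f[[2L]]))) {
        bad <- bad + 1L; next
      }
      pairs[[i]] <- trimws(f[1:2])
    }
  }
  if (bad > 0L) warning(bad, " malformed annotation row(s) skipped")
  pairs <- pairs[!vapply(pairs, is.null, logical(1))]
  if (!length(pairs)) stop("no usable annotation rows in ", path, call. = FALSE)
  genes <- vapply(pairs, `[[`, "", 1L)
  terms <- vapply(pairs, `[[`, "", 2L)
  gene_ids <- unique(genes)
  direct <- lapply(stats::setNames(gene_ids, gene_ids),
                   function(g) unique(terms[genes == g]))
  new_annotation_set(gene_ids, direct)
}

#' Construct an annotation set from in-memory lists
#'
#' @param genes ordered character vector of gene ids.
#' @param direct named list mapping each gene to a character vector of
#'   most-specific term ids (missing genes get no annotations).
#' @param unfolded optional named list of unfolded closures (ontology-tagged
#'   term labels), normally filled by [unfold_annotations()].
#' @return an `"annotation_set"` object.
#' @export
new_annotation_set <- function(genes, direct, unfolded = NULL) {
  direct <- lapply(stats::setNames(genes, genes), function(g) {
    v <- direct[[g]]
    if (is.null(v)) character(0) else unique(as.character(v))
  })
  structure(list(genes = genes, direct = direct, unfolded = unfolded),
            class = "annotation_set")
}

#' Unfold direct annotations to ancestor closures
#'
#' Replaces each gene's most-specific terms with their full ancestor closure
#' in the corresponding ontology DAG (the direct term itself included),
#' pooling over all supplied ontologies. Each direct term is resolved to the
#' first ontology that contains it; terms annotated to obsolete ids are
#' remapped through `replaced_by` when available, otherwise dropped with a
#' warning. Unfolding an already-unfolded set is a no-op (the closure is
#' idempotent).
#'
#' @param annotations an `"annotation_set"`.
#' @param ontologies a single `"ontology"` or a list of them.
#' @return the annotation set with `unfolded` filled: a named list mapping
#'   each gene to a character vector of `"<ontology_id>|<term_id>"` labels.
#' @export
unfold_annotations <- function(annotations, ontologies) {
  stopifnot(inherits(annotations, "annotation_set"))
  ontologies <- .as_ontology_list(ontologies)
  closures <- lapply(ontologies, function(o)
    .ancestor_sets(o$parents))
  dropped <- 0L
  unfolded <- lapply(annotations$direct, function(terms) {
    out <- character(0)
    for (t in terms) {
      hit <- FALSE
      for (o in ontologies) {
        t2 <- t
        if (!(t2 %in% o$terms) && t2 %in% names(o$replaced_by))
          t2 <- o$replaced_by[[t2]]
        if (t2 %in% o$terms) {
          cl <- c(t2, closures[[o$id]][[t2]])
          out <- c(out, paste(o$id, cl, sep = "|"))
          hit <- TRUE
          break
        }
      }
      if (!hit) dropped <<- dropped + 1L
    }
    unique(out)
  })
  if (dropped > 0L)
    warning(dropped, " direct annotation(s) to unresolvable terms dropped")
  annotations$unfolded <- unfolded
  annotations
}

.as_ontology_list <- function(ontologies) {
  if (inherits(ontologies, "ontology")) ontologies <- list(ontologies)
  stopifnot(all(vapply(ontologies, inherits, logical(1), "ontology")))
  ids <- vapply(ontologies, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("ontology ids must be unique", call. = FALSE)
  stats::setNames(ontologies, ids)
}

#' Build the binary and weighted annotation matrices
#'
#' Pools the terms of all supplied ontologies into one column space and
#' builds two sparse gene x term matrices over the unfolded annotations: the
#' binary matrix `B` (`B[g,t] = 1` iff term `t` is in gene `g`'s unfolded
#' closure) and the weighted matrix `W` obtained by replacing each one-entry
#' of `B` with the structure-based information content ([ic_struct()]) of
#' the corresponding term.
#'
#' @param annotations an unfolded `"annotation_set"` (see
#'   [unfold_annotations()]; direct-only sets are unfolded on the fly).
#' @param ontologies a single `"ontology"` or a list of them.
#' @return an object of class `"annotation_matrices"`: list with `genes`,
#'   `terms` (pooled `"<ontology_id>|<term_id>"` column labels), sparse
#'   matrices `B` and `W` (`Matrix::dgCMatrix`), and `ic` (per-column
#'   information content).
#' @export
annotation_matrices <- function(annotations, ontologies) {
  stopifnot(inherits(annotations, "annotation_set"))
  ontologies <- .as_ontology_list(ontologies)
  if (is.null(annotations$unfolded))
    annotations <- unfold_annotations(annotations, ontologies)
  genes <- annotations$genes
  if (!length(genes)) stop("annotation set contains no genes", call. = FALSE)
  cols <- unlist(lapply(ontologies, function(o) paste(o$id, o$terms, sep = "|")),
                 use.names = FALSE)
  ic <- unlist(lapply(ontologies, function(o) as.numeric(ic_struct(o))),
               use.names = FALSE)
  names(ic) <- cols
  gi <- rep(seq_along(genes), lengths(annotations$unfolded[genes]))
  tj <- match(unlist(annotations$unfolded[genes], use.names = FALSE), cols)
  keep <- !is.na(tj)
  B <- Matrix::sparseMatrix(i = gi[keep], j = tj[keep], x = 1,
                            dims = c(length(genes), length(cols)),
                            dimnames = list(genes, cols))
  W <- B %*% Matrix::Diagonal(length(cols), ic)
  W <- methods::as(Matrix::drop0(W), "CsparseMatrix")
  dimnames(W) <- dimnames(B)
  structure(list(genes = genes, terms = cols, B = B, W = W, ic = ic),
            class = "annotation_matrices")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set: ", length(x$genes), " genes, ",
      sum(lengths(x$direct)), " direct gene-term pairs",
      if (!is.null(x$unfolded)) paste0(", ", sum(lengths(x$unfolded)),
                                       " unfolded pairs"),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.annotation_matrices <- function(x, ...) {
  cat("Annotation matrices: ", length(x$genes), " genes x ", length(x$terms),
      " pooled terms (", Matrix::nnzero(x$B), " nonzero entries in B)\n",
      sep = "")
  invisible(x)
}

#' Export annotation matrices as Matrix Market files
#'
#' Writes `B.mtx`, `W.mtx` and the row/column label TSVs into `dir`.
#'
#' @param matrices an `"annotation_matrices"` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_annotation_matrices <- function(matrices, dir) {
  stopifnot(inherits(matrices, "annotation_matrices"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("B.mtx", "W.mtx", "genes.tsv", "terms.tsv"))
  Matrix::writeMM(matrices$B, paths[[1L]])
  Matrix::writeMM(matrices$W, paths[[2L]])
  writeLines(matrices$genes, paths[[3L]])
  writeLines(matrices$terms, paths[[4L]])
  invisible(paths)
}
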