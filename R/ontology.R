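#' @useDynLib gislasso, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef predict fitted residuals
NULL

# ---- internal graph machinery -------------------------------------------

# Kahn topological order over a parent-list graph (edges child -> parent).
# Returns term ids ordered so that every parent precedes its children;
# errors naming a cycle member if the filtered graph is not a DAG.
.topo_order <- function(parents) {
  terms <- names(parents)
  n_par <- lengths(parents)
  children <- .reverse_adjacency(parents)
  order <- character(0)
  queue <- terms[n_par == 0L]
  n_remaining <- n_par
  names(n_remaining) <- terms
  while (length(queue)) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    order <- c(order, t)
    for (ch in children[[t]]) {
      n_remaining[[ch]] <- n_remaining[[ch]] - 1L
      if (n_remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(terms)) {
    bad <- setdiff(terms, order)
    stop("cycle detected in the filtered ontology graph (involves term '",
         bad[[1L]], "')", call. = FALSE)
  }
  order
}

.reverse_adjacency <- function(parents) {
  terms <- names(parents)
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  children
}

# depth = longest path (in edges) from any root; roots have depth 0
.compute_depth <- function(parents, topo = NULL) {
  if (is.null(topo)) topo <- .topo_order(parents)
  depth <- stats::setNames(integer(length(topo)), topo)
  for (t in topo) {
    ps <- parents[[t]]
    depth[[t]] <- if (length(ps)) max(depth[ps]) + 1L else 0L
  }
  depth
}

# number of DISTINCT terms reachable against edge direction, self excluded
.count_descendants <- function(parents, topo = NULL) {
  if (is.null(topo)) topo <- .topo_order(parents)
  children <- .reverse_adjacency(parents)
  idx <- stats::setNames(seq_along(topo), topo)
  desc_sets <- vector("list", length(topo))
  for (t in rev(topo)) {
    ch <- children[[t]]
    if (length(ch)) {
      s <- idx[ch]
      for (c in ch) s <- c(s, desc_sets[[idx[[c]]]])
      desc_sets[[idx[[t]]]] <- unique(s)
    } else {
      desc_sets[[idx[[t]]]] <- integer(0)
    }
  }
  stats::setNames(lengths(desc_sets), topo)
}

# full ancestor closure (excluding the term itself) for every term
.ancestor_sets <- function(parents, topo = NULL) {
  if (is.null(topo)) topo <- .topo_order(parents)
  anc <- stats::setNames(vector("list", length(topo)), topo)
  for (t in topo) {
    ps <- parents[[t]]
    anc[[t]] <- if (length(ps)) unique(c(ps, unlist(anc[ps], use.names = FALSE))) else character(0)
  }
  anc
}

# shared constructor for parsed and simulated ontologies
.new_ontology <- function(id, parents, term_names = NULL,
                          relationship_filter = c("is_a", "part_of"),
                          replaced_by = character(0)) {
  terms <- names(parents)
  if (!length(terms)) stop("ontology '", id, "' has no usable terms", call. = FALSE)
  for (t in terms) {
    if (t %in% parents[[t]])
      stop("term '", t, "' lists itself as a parent", call. = FALSE)
  }
  topo <- .topo_order(parents)
  depth <- .compute_depth(parents, topo)
  n_desc <- .count_descendants(parents, topo)
  structure(list(
    id = id,
    terms = terms,
    term_names = term_names,
    parents = parents,
    relationship_filter = relationship_filter,
    depth = depth[terms],
    n_descendants = n_desc[terms],
    max_depth = max(depth),
    total_terms = length(terms),
    replaced_by = replaced_by
  ), class = "ontology")
}

# ---- OBO parsing ---------------------------------------------------------

#' Read an OBO ontology into a DAG with structural statistics
#'
#' Parses an OBO 1.2/1.4 flat file into a directed acyclic graph of terms,
#' keeping only the relationship types in `relationships` (edges point from
#' a term to its parents). Obsolete terms are excluded from all statistics;
#' their `replaced_by` targets are recorded so annotations can be remapped.
#' For every non-obsolete term the constructor computes its depth (length of
#' the longest path from any root, roots at depth 0) and its number of
#' distinct descendants, together with the ontology-wide maximum depth and
#' term count used by [ic_struct()].
#'
#' @param path path to an OBO flat file (`[Term]` stanzas; the `id`, `name`,
#'   `is_a`, `relationship`, `is_obsolete` and `replaced_by` tags are honored).
#' @param relationships character vector of relationship-type labels to keep
#'   when building the graph; `"is_a"` refers to the dedicated `is_a` tag.
#' @param id label for the ontology (defaults to the file name without
#'   extension).
#' @return an object of class `"ontology"`: a list with elements `terms`,
#'   `parents` (filtered parent lists), `depth`, `n_descendants`,
#'   `max_depth`, `total_terms`, `relationship_filter` and `replaced_by`.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: T:1", "name: root",
#'              "[Term]", "id: T:2", "name: leaf", "is_a: T:1 ! root"), obo)
#' ont <- read_obo(obo)
#' ont$max_depth
#' @export
read_obo <- function(path, relationships = c("is_a", "part_of"), id = NULL) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path, call. = FALSE)
  if (!length(relationships)) stop("'relationships' must be non-empty", call. = FALSE)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)

  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function() if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <<- cur
  for (line in lines) {
    line <- sub("\\s*!.*$", "", line)          # trailing comments
    line <- sub("\\{[^}]*\\}\\s*$", "", line)  # trailing qualifier blocks
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush()
      in_term <- identical(line, "[Term]")
      cur <- if (in_term) list(parents = list()) else NULL
      next
    }
    if (!in_term) next
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1L]]
    if (length(m) < 3L) next
    tag <- m[[2L]]; val <- trimws(m[[3L]])
    switch(tag,
      id = { cur$id <- val },
      name = { cur$name <- val },
      is_a = { cur$parents[["is_a"]] <- c(cur$parents[["is_a"]], val) },
      relationship = {
        parts <- strsplit(val, "\\s+")[[1L]]
        if (length(parts) >= 2L)
          cur$parents[[parts[[1L]]]] <- c(cur$parents[[parts[[1L]]]], parts[[2L]])
      },
      is_obsolete = { cur$obsolete <- tolower(val) %in% c("true", "1") },
      replaced_by = { cur$replaced_by <- val },
      NULL)
  }
  flush()

  stanzas <- Filter(function(s) !is.null(s$id), stanzas)
  if (!length(stanzas)) stop("no [Term] stanzas found in ", path, call. = FALSE)
  ids <- vapply(stanzas, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    keep <- !duplicated(ids)
    warning("duplicate term ids in ", path, "; keeping first occurrence")
    stanzas <- stanzas[keep]; ids <- ids[keep]
  }
  obsolete <- vapply(stanzas, function(s) isTRUE(s$obsolete), logical(1))
  alive <- ids[!obsolete]
  replaced_by <- unlist(lapply(stanzas[obsolete], function(s)
    if (!is.null(s$replaced_by)) stats::setNames(s$replaced_by, s$id)))
  if (is.null(replaced_by)) replaced_by <- character(0)

  parents <- stats::setNames(vector("list", length(alive)), alive)
  term_names <- stats::setNames(character(length(alive)), alive)
  dropped_edges <- 0L
  for (s in stanzas[!obsolete]) {
    term_names[[s$id]] <- if (!is.null(s$name)) s$name else s$id
    ps <- unique(unlist(s$parents[intersect(names(s$parents), relationships)],
                        use.names = FALSE))
    known <- ps %in% alive
    dropped_edges <- dropped_edges + sum(!known)
    parents[s$id] <- list(ps[known])  # [[<- would drop zero-length entries
  }
  if (dropped_edges > 0L)
    warning(dropped_edges, " edge(s) to unknown or obsolete terms dropped")

  .new_ontology(id, parents, term_names, relationships, replaced_by)
}

# ---- accessors and statistics -------------------------------------------

#' Term depths of an ontology
#'
#' Depth of each non-obsolete term: the number of edges on the longest path
#' from any root (a term with no parents under the relationship filter) down
#' to the term; roots have depth 0.
#'
#' @param ontology an `"ontology"` object.
#' @return named integer vector over the ontology's terms.
#' @export
term_depth <- function(ontology) {
  stopifnot(inherits(ontology, "ontology"))
  ontology$depth
}

#' Descendant counts of an ontology
#'
#' Number of distinct non-obsolete terms reachable from each term against the
#' parent direction (terms having it as an ancestor), excluding the term
#' itself. Terms reachable along several paths are counted once.
#'
#' @inheritParams term_depth
#' @return named integer vector over the ontology's terms.
#' @export
term_descendants <- function(ontology) {
  stopifnot(inherits(ontology, "ontology"))
  ontology$n_descendants
}

#' Ancestor closure of terms
#'
#' All ancestors of the given terms under the ontology's relationship filter,
#' at any distance, including the terms themselves (a term belongs to its own
#' closure).
#'
#' @inheritParams term_depth
#' @param terms character vector of term ids present in the ontology.
#' @return character vector of term ids (unique, unordered).
#' @export
term_ancestors <- function(ontology, terms) {
  stopifnot(inherits(ontology, "ontology"))
  missing <- setdiff(terms, ontology$terms)
  if (length(missing))
    stop("term(s) not in ontology '", ontology$id, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- terms
  frontier <- terms
  while (length(frontier)) {
    frontier <- setdiff(unique(unlist(ontology$parents[frontier], use.names = FALSE)), out)
    out <- c(out, frontier)
  }
  out
}

#' Structure-based information content of ontology terms
#'
#' Scores each term by how specific its position in the DAG is:
#' \deqn{IC_{struct}(t) = \frac{depth(t)}{max\_depth}\Bigl(1 -
#'   \frac{\log(desc(t)+1)}{\log(total\_terms)}\Bigr)}
#' where `depth(t)` is the longest-path depth of the term, `desc(t)` its
#' number of distinct descendants, and `max_depth`/`total_terms` the
#' ontology-wide statistics. Values lie in `[0, 1]`: roots score exactly 0,
#' and a childless term at the maximum depth scores exactly 1. The log ratio
#' makes the score invariant to the logarithm base (natural log is used).
#'
#' @inheritParams term_depth
#' @param terms character vector of term ids; default all terms.
#' @return named numeric vector of scores in `[0, 1]`.
#' @examples
#' ont <- sim_ontology(n_terms = 30, seed = 1)
#' range(ic_struct(ont))
#' @export
ic_struct <- function(ontology, terms = NULL) {
  stopifnot(inherits(ontology, "ontology"))
  if (ontology$total_terms < 2L || ontology$max_depth < 1L)
    stop("degenerate ontology: need at least 2 terms and max depth >= 1 ",
         "for a meaningful structure-based information content", call. = FALSE)
  if (is.null(terms)) terms <- ontology$terms
  missing <- setdiff(terms, ontology$terms)
  if (length(missing))
    stop("term(s) not in ontology '", ontology$id, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  d <- ontology$depth[terms]
  ds <- ontology$n_descendants[terms]
  ic <- (d / ontology$max_depth) *
    (1 - log(ds + 1) / log(ontology$total_terms))
  stats::setNames(pmin(pmax(as.numeric(ic), 0), 1), terms)
}

#' Per-term structural statistics table
#'
#' @inheritParams term_depth
#' @return data frame with columns `term_id`, `depth`, `n_descendants`,
#'   `ic_struct`, suitable for writing as TSV.
#' @export
ontology_stats <- function(ontology) {
  stopifnot(inherits(ontology, "ontology"))
  data.frame(term_id = ontology$terms,
             depth = as.integer(ontology$depth),
             n_descendants = as.integer(ontology$n_descendants),
             ic_struct = as.numeric(ic_struct(ontology)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.ontology <- function(x, ...) {
  cat("Ontology '", x$id, "': ", x$total_terms, " terms, max depth ",
      x$max_depth, "\n", sep = "")
  cat("  relationships: ", paste(x$relationship_filter, collapse = ", "), "\n",
      sep = "")
  roots <- sum(lengths(x$parents) == 0L)
  cat("  roots: ", roots, "; leaves: ", sum(x$n_descendants == 0L), "\n", sep = "")
  invisible(x)
}
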