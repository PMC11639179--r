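# Independent brute-force oracles and small fixture builders used across the
# test files. These deliberately avoid the package's own graph code paths.

# longest root-to-term path length by exhaustive recursion over parent lists
brute_depth <- function(parents, term) {
  ps <- parents[[term]]
  if (!length(ps)) return(0L)
  1L + max(vapply(ps, function(p) brute_depth(parents, p), integer(1)))
}

# distinct terms reachable against the parent direction, self excluded
brute_descendants <- function(parents, term) {
  terms <- names(parents)
  reach <- function(t) {
    kids <- terms[vapply(terms, function(s) t %in% parents[[s]], logical(1))]
    unique(c(kids, unlist(lapply(kids, reach))))
  }
  length(unique(reach(term)))
}

# random layered DAG as a bare parent list (edges only to earlier terms)
random_parent_list <- function(n_terms, p_edge = 0.25) {
  ids <- paste0("N", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  for (i in seq_len(n_terms)[-1]) {
    earlier <- ids[seq_len(i - 1L)]
    ps <- earlier[stats::runif(i - 1L) < p_edge]
    if (!length(ps)) ps <- sample(earlier, 1L)
    parents[[ids[i]]] <- ps
  }
  parents
}

# write a parent list as a minimal OBO file; rel = tag used for every edge
write_toy_obo <- function(parents, path = tempfile(fileext = ".obo"),
                          rel = "is_a", obsolete = character(0),
                          replaced_by = character(0)) {
  lines <- character(0)
  for (t in names(parents)) {
    lines <- c(lines, "[Term]", paste0("id: ", t), paste0("name: term ", t))
    for (p in parents[[t]]) {
      lines <- c(lines, if (rel == "is_a") paste0("is_a: ", p, " ! parent")
                 else paste0("relationship: ", rel, " ", p, " ! parent"))
    }
    if (t %in% obsolete) {
      lines <- c(lines, "is_obsolete: true")
      if (t %in% names(replaced_by))
        lines <- c(lines, paste0("replaced_by: ", replaced_by[[t]]))
    }
  }
  writeLines(lines, path)
  path
}

# dense row-scan Gene Information Score oracle
brute_gis <- function(W) {
  apply(as.matrix(W), 1L, function(row) {
    pos <- row[row > 0]
    if (!length(pos)) 0 else mean(pos)
  })
}

# exhaustive 2-feature grid search of the penalized objective
grid_min_objective <- function(x, y, lambda, pf, family, lim = 3, steps = 201) {
  grid <- seq(-lim, lim, length.out = steps)
  best <- Inf
  for (b1 in grid) for (b2 in grid) {
    v <- wlasso_objective(c(b1, b2), 0, x, y, lambda, pf, family)
    if (v < best) best <- v
  }
  best
}
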