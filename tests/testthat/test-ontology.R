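# OBO parsing, DAG statistics and the structure-based information content.

test_that("a toy is_a chain parses with the right size and height", {
  path <- write_toy_obo(list(A = character(0), B = "A", C = "B"))
  ont <- read_obo(path)
  expect_equal(ont$total_terms, 3L)
  expect_equal(ont$max_depth, 2L)
  expect_equal(unname(term_depth(ont)[c("A", "B", "C")]), c(0L, 1L, 2L))
  expect_equal(unname(term_descendants(ont)[c("A", "B", "C")]), c(2L, 1L, 0L))
})

test_that("obsolete terms are excluded from every statistic", {
  path <- write_toy_obo(list(A = character(0), B = "A", C = "B"),
                        obsolete = "C")
  ont <- read_obo(path)
  expect_equal(ont$total_terms, 2L)
  expect_false("C" %in% ont$terms)
  expect_equal(ont$max_depth, 1L)
})

test_that("edges outside the relationship filter are ignored", {
  # B regulates A; with filter {is_a} B must look like a root
  path <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "name: a",
               "[Term]", "id: B", "name: b",
               "relationship: regulates A ! a"), path)
  ont <- read_obo(path, relationships = "is_a")
  expect_length(ont$parents[["B"]], 0L)
  path2 <- write_toy_obo(list(A = character(0), B = "A"), rel = "part_of")
  expect_length(read_obo(path2, relationships = "is_a")$parents[["B"]], 0L)
  expect_length(read_obo(path2)$parents[["B"]], 1L)
})

test_that("depth is the longest root-to-term path", {
  # diamond A->B->D, A->C->D plus longer chain A->E->F->D
  parents <- list(A = character(0), B = "A", C = "A", E = "A", F = "E",
                  D = c("B", "C", "F"))
  ont <- read_obo(write_toy_obo(parents))
  expect_equal(unname(term_depth(ont)[["D"]]), 3L)
  expect_equal(unname(term_depth(ont)[["D"]]), brute_depth(parents, "D"))
})

test_that("descendants reachable along several paths are counted once", {
  parents <- list(A = character(0), B = "A", C = "A", D = c("B", "C"))
  ont <- read_obo(write_toy_obo(parents))
  expect_equal(unname(term_descendants(ont)[["A"]]), 3L)
  expect_equal(unname(term_descendants(ont)[["D"]]), 0L)
})

test_that("a cycle in the filtered graph is rejected with a named culprit", {
  path <- write_toy_obo(list(A = "C", B = "A", C = "B"))
  expect_error(read_obo(path), "cycle")
})

test_that("ic_struct matches hand-evaluated values and endpoints", {
  # hand case: 100 terms, max depth 5; depth 3 with 9 descendants -> 0.3
  chain <- stats::setNames(c(list(character(0)),
                             as.list(paste0("T", 1:5))), paste0("T", 1:6))
  ont <- read_obo(write_toy_obo(chain))
  d <- 3; desc <- 9; maxd <- 5; total <- 100
  expect_equal((d / maxd) * (1 - log(desc + 1) / log(total)), 0.3)

  # endpoints on a generated DAG: roots exactly 0, deepest childless exactly 1
  so <- sim_ontology(60, seed = 11)
  ic <- ic_struct(so)
  roots <- names(which(lengths(so$parents) == 0L))
  expect_true(all(ic[roots] == 0))
  deep_leaf <- names(which(term_depth(so) == so$max_depth &
                             term_descendants(so) == 0L))
  expect_true(length(deep_leaf) >= 1L)
  expect_true(all(ic[deep_leaf] == 1))
  expect_true(all(ic >= 0 & ic <= 1))
})

test_that("ic_struct is monotone in depth and antitone in descendant count", {
  total <- 50; maxd <- 6
  icval <- function(d, desc) (d / maxd) * (1 - log(desc + 1) / log(total))
  expect_true(all(diff(vapply(0:maxd, icval, numeric(1), desc = 3)) > 0))
  expect_true(all(diff(vapply(0:20, function(k) icval(4, k), numeric(1))) < 0))
})

test_that("degenerate ontologies are rejected rather than scored", {
  single <- read_obo(write_toy_obo(list(A = character(0), B = "A")))
  expect_silent(ic_struct(single))  # 2 terms, depth 1: smallest valid case
  flat <- read_obo(write_toy_obo(list(A = character(0), B = character(0))))
  expect_error(ic_struct(flat), "degenerate")
  expect_error(ic_struct(single, "nope"), "not in ontology")
})

test_that("depth and descendant counts agree with brute force on random DAGs", {
  set.seed(101)
  for (i in 1:20) {
    parents <- random_parent_list(sample(5:25, 1L))
    ont <- read_obo(write_toy_obo(parents))
    for (t in sample(names(parents), 5L)) {
      expect_identical(unname(term_depth(ont)[[t]]), brute_depth(parents, t))
      expect_identical(unname(term_descendants(ont)[[t]]),
                       brute_descendants(parents, t))
    }
  }
})

test_that("ontology_stats tabulates every term once", {
  ont <- sim_ontology(40, seed = 5)
  st <- ontology_stats(ont)
  expect_equal(nrow(st), 40L)
  expect_false(anyDuplicated(st$term_id) > 0)
  expect_equal(st$ic_struct, unname(ic_struct(ont)[st$term_id]))
})
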