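# Synthetic-data generators and the sensitivity-analysis harnesses.

test_that("simulated ontologies are single-root, reachable and deterministic", {
  two <- sim_ontology(2, seed = 1)
  expect_equal(two$total_terms, 2L)
  expect_equal(two$max_depth, 1L)
  a <- sim_ontology(80, depth_target = 6, seed = 9)
  b <- sim_ontology(80, depth_target = 6, seed = 9)
  expect_identical(a$parents, b$parents)
  expect_equal(sum(lengths(a$parents) == 0L), 1L)   # single root
  expect_gte(a$max_depth, 6L)
  root <- names(which(lengths(a$parents) == 0L))
  expect_equal(unname(term_descendants(a)[[root]]), a$total_terms - 1L)
  big <- sim_ontology(500, depth_target = 8, seed = 10)
  expect_equal(sum(lengths(big$parents) == 0L), 1L)
  expect_gte(big$max_depth, 8L)
})

test_that("annotation generation hits the unannotated fraction exactly", {
  ont <- sim_ontology(60, seed = 2)
  genes <- paste0("g", 1:100)
  ann <- sim_annotations(genes, ont, frac_unannotated = 0.2, seed = 3)
  expect_equal(sum(lengths(ann$direct) == 0L), 20L)
  ann2 <- sim_annotations(genes, ont, frac_unannotated = 0.2, seed = 3)
  expect_identical(ann$direct, ann2$direct)
  am <- annotation_matrices(ann, ont)
  expect_equal(sum(gene_information_score(am) == 0), 20L)
})

test_that("richer annotation draws unfold toward larger closures", {
  ont <- sim_ontology(80, seed = 4)
  genes <- paste0("g", 1:40)
  lean <- annotation_matrices(
    sim_annotations(genes, ont, mean_terms_per_gene = 1,
                    frac_unannotated = 0, seed = 5), ont)
  rich <- annotation_matrices(
    sim_annotations(genes, ont, mean_terms_per_gene = 8,
                    frac_unannotated = 0, seed = 5), ont)
  expect_gt(mean(Matrix::rowSums(rich$B)), mean(Matrix::rowSums(lean$B)))
})

test_that("expression generation is deterministic and null data is null", {
  d1 <- sim_expression(50, 20, cbind(1, 2), seed = 6)
  d2 <- sim_expression(50, 20, cbind(1, 2), seed = 6)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$y, d2$y)
  null <- sim_expression(144, 10, NULL, seed = 7)
  expect_true(abs(mean(null$y) - 0.5) < 0.15)
})

test_that("a huge effect dominates the Fisher ranking in most draws", {
  hits <- 0L
  for (s in 1:20) {
    d <- sim_expression(60, 15, cbind(3, 10), seed = 500 + s)
    fs <- fisher_score(d$x, d$y)
    hits <- hits + as.integer(which.max(fs) == 3L)
  }
  expect_gte(hits, 19L)
})

test_that("Fisher's score matches hand arithmetic and flags degeneracy", {
  x <- matrix(c(0, 0, 0, 1, 1, 2), ncol = 1)
  y <- rep(c("a", "b"), each = 3)
  # by hand: means 0 and 4/3, overall 2/3; ML variances 0 and 2/9
  # numerator 3*(2/3)^2 + 3*(2/3)^2 = 8/3, denominator 3*(2/9) = 2/3 -> 4
  expect_equal(unname(fisher_score(x, y)), 4)
  same <- matrix(rep(1:3, 2), ncol = 1)
  expect_equal(unname(fisher_score(same, y)), 0)
  indicator <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 1)
  expect_warning(fs <- fisher_score(indicator, y), "Inf")
  expect_true(is.infinite(fs))
})

test_that("controlled datasets respect both correlation caps", {
  d <- sim_expression(100, 400, cbind(c(1, 2, 3), c(2, 1, 0.5)), seed = 8)
  cd <- controlled_dataset(d, n_seed_features = 5, n_fill = 95, seed = 9)
  expect_equal(ncol(cd$x), 100L)
  expect_length(cd$seed_features, 5L)
  seed_cor <- stats::cor(cd$x[, cd$seed_features])
  expect_true(all(abs(seed_cor[upper.tri(seed_cor)]) < 0.5))
  fill <- setdiff(colnames(cd$x), cd$seed_features)
  cross <- abs(stats::cor(cd$x[, fill[1:20]], cd$x[, cd$seed_features]))
  expect_true(all(cross < 0.5))
  expect_error(
    controlled_dataset(sim_expression(30, 20, NULL, seed = 1), n_fill = 500),
    "unsatisfiable")
})

test_that("noisy copies have the advertised geometry", {
  d <- sim_expression(50, 10, cbind(1, 2), seed = 10)
  dc <- add_noisy_copies(d, "g1", n_copies = 10, noise_sd = 0.01, seed = 11)
  expect_equal(ncol(dc$x), 20L)
  expect_equal(dc$block, c("g1_0", paste0("g1_", 1:10)))
  expect_gt(min(stats::cor(dc$x[, "g1_0"], dc$x[, dc$block[-1]])), 0.99)
  exact <- add_noisy_copies(d, "g1", n_copies = 2, noise_sd = 0, seed = 11)
  expect_equal(exact$x[, "g1_1"], exact$x[, "g1_0"], ignore_attr = TRUE)
})

test_that("scenario penalty ladders have exact endpoints and uniform spacing", {
  sc <- gis_scenarios(0.8)
  expect_equal(sc$NO_GIS$original_w, 1)
  expect_true(all(sc$NO_GIS$copy_w == 1) && all(sc$GIS1$copy_w == 1))
  expect_equal(sc$GIS1$original_w, 0.8)
  expect_equal(sc$GIS2$copy_w[c(1, 10)], c(0.95, 1.0))
  expect_equal(sc$GIS3$copy_w[c(1, 10)], c(0.8, 1.0))
  expect_equal(sc$GIS4$copy_w[c(1, 10)], c(0.5, 1.0))
  for (s in sc[c("GIS2", "GIS3", "GIS4")])
    expect_lt(max(abs(diff(diff(s$copy_w)))), 1e-12)
})

test_that("the multicollinearity harness is deterministic and bounded", {
  d <- sim_expression(60, 12, cbind(1, 3), seed = 12)
  r1 <- run_multicollinearity(d, "g1", lambda = 0.2, reps = 3, seed = 13)
  r2 <- run_multicollinearity(d, "g1", lambda = 0.2, reps = 3, seed = 13)
  expect_identical(r1$count, r2$count)
  expect_true(all(r1$count >= 0 & r1$count <= 3))
  one <- run_multicollinearity(d, "g1", lambda = 0.2, reps = 1, seed = 13)
  expect_true(all(one$count %in% 0:1))
  # a strongly predictive duplicated block is always selected somewhere
  no_gis <- subset(r1, scenario == "NO_GIS")
  expect_gt(sum(no_gis$count), 0)
})

test_that("with exact duplicates the smallest penalty wins the block", {
  # strong feature, zero-noise copies, GIS4 ladder, strong regularization:
  # whenever one block member is selected it must be the cheapest (copy _1
  # has penalty 0.5 < original's own penalty here)
  d <- sim_expression(80, 6, cbind(1, 4), seed = 14)
  dc <- add_noisy_copies(d, "g1", n_copies = 10, noise_sd = 0, seed = 15)
  sc <- gis_scenarios(0.9)$GIS4
  pf <- stats::setNames(rep(1, ncol(dc$x)), colnames(dc$x))
  pf["g1_0"] <- sc$original_w
  pf[paste0("g1_", 1:10)] <- sc$copy_w
  fit <- wlasso(dc$x, dc$y, lambda = 0.9, penalty.factor = pf,
                family = "binomial", lambda.scale = "sum")
  hit <- intersect(fit$selected, dc$block)
  expect_true(length(hit) >= 1L)
  expect_true("g1_1" %in% hit)   # the 0.5-penalty copy
})

test_that("predictive-power overrides reproduce the baseline exactly", {
  d <- sim_expression(60, 8, cbind(1, 2), seed = 16)
  base <- run_predictive_power(d, data.frame(gene = "g1", w = 1),
                               lambda = 0.2, reps = 3, seed = 17)
  again <- run_predictive_power(d, data.frame(gene = "g1", w = 1),
                                lambda = 0.2, reps = 3, seed = 17)
  expect_identical(base, again)
  expect_error(run_predictive_power(d, data.frame(gene = "g1", w = 1.5),
                                    reps = 1), "\\(0, 1\\]")
})
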