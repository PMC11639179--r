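# The weighted-LASSO solver: objective, degeneracy to the standard LASSO,
# rescaling equivalence, KKT certificates and the S3 surface.

sim_xy <- function(n = 60, q = 10, family = "gaussian", seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * q), n, q, dimnames = list(NULL, paste0("g", seq_len(q))))
  eta <- drop(x[, 1:3] %*% c(1.5, -1, 0.8))
  y <- if (family == "binomial") rbinom(n, 1, plogis(eta)) else eta + rnorm(n)
  list(x = x, y = y)
}

test_that("soft thresholding shrinks and truncates", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  z <- rnorm(10)
  expect_equal(soft_threshold(z, 0), z)
  expect_error(soft_threshold(1, -1), "non-negative")
})

test_that("objective has the null-model closed form and lambda = 0 is pure loss", {
  d <- sim_xy()
  yc <- d$y - mean(d$y)
  expect_equal(wlasso_objective(rep(0, 10), 0, d$x, yc, lambda = 0.3),
               sum(yc^2) / (2 * length(yc)))
  b <- rnorm(10)
  expect_equal(wlasso_objective(b, 0.2, d$x, d$y, lambda = 0),
               0.5 * mean((d$y - 0.2 - d$x %*% b)^2))
  # unit penalties equal the standard LASSO objective written out directly
  expect_equal(wlasso_objective(b, 0, d$x, d$y, lambda = 0.3),
               0.5 * mean((d$y - d$x %*% b)^2) + 0.3 * sum(abs(b)))
  expect_error(wlasso_objective(b[1:3], 0, d$x, d$y, 0.1), "dimension")
})

test_that("unit penalties reproduce glmnet for both families", {
  skip_if_not_installed("glmnet")
  for (family in c("gaussian", "binomial")) {
    d <- sim_xy(family = family, seed = 7)
    lam <- if (family == "gaussian") 0.08 else 0.04
    fit <- wlasso(d$x, d$y, lambda = lam, family = family, tol = 1e-10)
    ref <- glmnet::glmnet(d$x, d$y, family = family,
                          lambda = c(4, 2, 1) * lam, standardize = TRUE,
                          thresh = 1e-14)
    expect_lt(max(abs(fit$beta - ref$beta[, 3])), 1e-5)
    expect_lt(abs(fit$a0 - ref$a0[[3]]), 1e-5)
  }
})

test_that("weighted fits equal rescaled-column standard fits", {
  set.seed(42)
  for (family in c("gaussian", "binomial")) {
    for (i in 1:5) {
      d <- sim_xy(family = family, seed = 100 + i)
      w <- runif(10, 0.4, 1)
      lam <- if (family == "gaussian") 0.06 else 0.03
      direct <- wlasso(d$x, d$y, lambda = lam, penalty.factor = w,
                       family = family, standardize = FALSE, tol = 1e-10)
      rescaled <- wlasso(sweep(d$x, 2, w, "/"), d$y, lambda = lam,
                         family = family, standardize = FALSE, tol = 1e-10)
      expect_lt(max(abs(direct$beta - rescaled$beta / w)), 1e-5)
    }
  }
})

test_that("the null model appears exactly at the KKT threshold", {
  d <- sim_xy(seed = 3)
  w <- runif(10, 0.5, 1)
  g <- abs(drop(crossprod(d$x, d$y - mean(d$y)))) / nrow(d$x)
  lam_max <- max(g / w)
  above <- wlasso(d$x, d$y, lambda = lam_max * 1.001, penalty.factor = w,
                  standardize = FALSE)
  expect_length(above$selected, 0L)
  expect_equal(above$a0, mean(d$y))
  below <- wlasso(d$x, d$y, lambda = lam_max * 0.95, penalty.factor = w,
                  standardize = FALSE)
  expect_gt(length(below$selected), 0L)
})

test_that("the solver beats a 201 x 201 brute-force grid on 2-feature problems", {
  set.seed(5)
  for (family in c("gaussian", "binomial")) {
    x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
    y <- if (family == "binomial") rbinom(40, 1, plogis(x[, 1])) else
      x[, 1] - 0.5 * x[, 2] + rnorm(40, sd = 0.5)
    pf <- c(0.6, 1)
    lam <- 0.05
    fit <- wlasso(x, y, lambda = lam, penalty.factor = pf, family = family,
                  standardize = FALSE, intercept = FALSE, tol = 1e-10)
    obj_fit <- wlasso_objective(fit$beta, 0, x, y, lam, pf, family)
    expect_lte(obj_fit, grid_min_objective(x, y, lam, pf, family) + 1e-4)
  }
})

test_that("KKT conditions hold at every solution", {
  set.seed(9)
  for (family in c("gaussian", "binomial")) {
    for (i in 1:5) {
      d <- sim_xy(family = family, seed = 200 + i)
      w <- runif(10, 0.3, 1)
      fit <- wlasso(d$x, d$y, lambda = 0.05, penalty.factor = w,
                    family = family, tol = 1e-10)
      expect_true(all(kkt_check(fit, d$x, d$y, tol = 1e-5)$ok))
    }
  }
})

test_that("the objective path is non-increasing on random problems", {
  set.seed(13)
  for (i in 1:50) {
    family <- if (i %% 2) "gaussian" else "binomial"
    d <- sim_xy(n = 40, q = 8, family = family, seed = 300 + i)
    lam <- runif(1, 0.001, 0.3)
    w <- runif(8, 0, 1.5)
    fit <- wlasso(d$x, d$y, lambda = lam, penalty.factor = w, family = family)
    expect_true(all(diff(fit$objective_path) <= 1e-9))
  }
})

test_that("constant columns are excluded but reported", {
  d <- sim_xy()
  x <- cbind(d$x, flat = 1)
  expect_warning(fit <- wlasso(x, d$y, lambda = 0.05), "constant")
  expect_equal(unname(fit$beta[["flat"]]), 0)
  expect_equal(fit$excluded, "flat")
})

test_that("penalty factor zero leaves a feature unpenalized", {
  d <- sim_xy(seed = 17)
  w <- c(0, rep(1, 9))
  fit <- wlasso(d$x, d$y, lambda = 5, penalty.factor = w, standardize = FALSE)
  expect_true("g1" %in% fit$selected)     # unpenalized feature survives
  expect_length(setdiff(fit$selected, "g1"), 0L)
})

test_that("predict, coef, fitted and residuals are coherent", {
  d <- sim_xy(family = "binomial", seed = 19)
  fit <- wlasso(d$x, d$y, lambda = 0.02, family = "binomial")
  expect_equal(unname(coef(fit)[1]), fit$a0)
  eta <- predict(fit, d$x, type = "link")
  expect_equal(plogis(eta), predict(fit, d$x, type = "response"))
  expect_equal(as.integer(plogis(eta) > 0.5), predict(fit, d$x, type = "class"))
  expect_equal(residuals(fit), d$y - fitted(fit))
  expect_output(print(fit), "Weighted-LASSO")
  expect_output(print(summary(fit)), "Selected")
})

test_that("one-vs-rest multiclass separates well-separated classes", {
  set.seed(23)
  n <- 90
  cls <- rep(c("a", "b", "c"), each = n / 3)
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("g", 1:10)))
  x[cls == "a", 1] <- x[cls == "a", 1] + 5
  x[cls == "b", 2] <- x[cls == "b", 2] + 5
  fit <- wlasso_ovr(x, cls, lambda = 0.002)
  expect_equal(as.character(predict(fit, x)), cls)
  expect_true("g1" %in% fit$selected$a)
  expect_true("g2" %in% fit$selected$b)
  expect_error(wlasso_ovr(x[1:31, ], c(rep("a", 30), "b"), lambda = 0.1),
               "at least 2 samples")
})

test_that("selection sets aggregate union, intersection and frequency", {
  s <- selection_sets(list(c("a", "b"), c("b", "c")))
  expect_setequal(s$union, c("a", "b", "c"))
  expect_equal(s$intersection, "b")
  expect_equal(s$frequency[["b"]], 2L)
  one <- selection_sets(list(c("x", "y")))
  expect_equal(one$union, one$intersection)
})

test_that("cross-validation returns a sane table and honors tie-breaking", {
  d <- sim_xy(n = 80, family = "binomial", seed = 29)
  cv <- cv_wlasso(d$x, d$y, family = "binomial", lambda = c(0.02, 0.05),
                  nfolds = 4, seed = 31)
  expect_equal(nrow(cv$table), 2L)
  expect_true(cv$best_lambda %in% c(0.02, 0.05))
  # single-cell grid: best is that cell
  cv1 <- cv_wlasso(d$x, d$y, family = "binomial", lambda = 0.05,
                   nfolds = 4, seed = 31)
  expect_equal(nrow(cv1$table), 1L)
  expect_equal(cv1$best_lambda, 0.05)
  # fold sizes differ by at most one
  expect_lte(diff(range(table(cv$foldid))), 1)
  # exact metric ties must go to the larger lambda
  tab <- data.frame(lambda = c(0.1, 0.2), shape = 1,
                    metric_mean = c(0.8, 0.8))
  ord <- order(-tab$metric_mean, -tab$lambda, tab$shape)
  expect_equal(tab$lambda[ord[1]], 0.2)
})

test_that("pure-noise responses cross-validate near the majority rate", {
  set.seed(37)
  x <- matrix(rnorm(120 * 15), 120, 15, dimnames = list(NULL, paste0("g", 1:15)))
  y <- rbinom(120, 1, 0.5)
  cv <- cv_wlasso(x, y, family = "binomial", lambda = c(0.05, 0.1),
                  nfolds = 5, seed = 41)
  majority <- max(mean(y), 1 - mean(y))
  best <- max(cv$table$metric_mean)
  sd_best <- max(cv$table$metric_sd) / sqrt(5)
  expect_lt(best, majority + 3 * max(sd_best, 0.05))
})
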