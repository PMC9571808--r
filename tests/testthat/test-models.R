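# Evaluation heads: metrics, CV-SVM, LDA projection, PLSR calibration.

test_that("metrics reproduce the hand-computed values", {
  m <- compute_metrics(c(0, 1, 2), c(0, 1, 5))
  expect_equal(m$rmse, sqrt(3))  # SS_res 9 over n = 3
  expect_equal(m$r2, -3.5)       # 1 - 9/2
  perfect <- compute_metrics(1:10, 1:10)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)
  # predicting the mean gives R2 = 0 by definition
  y <- c(2, 4, 9, 1)
  expect_equal(compute_metrics(y, rep(mean(y), 4))$r2, 0)
  expect_error(compute_metrics(1:3, 1:4), "length")
  expect_error(compute_metrics(rep(2, 5), rnorm(5)), "zero-variance")
})

test_that("separable classes are classified perfectly", {
  d <- separable_classes()
  rep_q <- svm_crossval(d$x, d$y, kernel = "quadratic", folds = 4,
                        seed = 1)
  rep_l <- svm_crossval(d$x, d$y, kernel = "linear", folds = 4, seed = 1)
  for (r in list(rep_q, rep_l)) {
    expect_equal(r$accuracy, 100)
    expect_true(all(r$confusion == diag(12, 4)))
    expect_equal(unname(r$class_rate), rep(100, 4))
  }
})

test_that("confusion matrix structure is consistent", {
  d <- separable_classes(shift = 1.2)  # overlapping classes
  r <- svm_crossval(d$x, d$y, folds = 4, seed = 2)
  expect_equal(rowSums(r$confusion), table(d$y), ignore_attr = TRUE)
  expect_equal(unname(rowSums(r$confusion_pct)), rep(100, 4))
  expect_equal(r$accuracy, 100 * sum(diag(r$confusion)) / length(d$y))
  # determinism
  r2 <- svm_crossval(d$x, d$y, folds = 4, seed = 2)
  expect_identical(r$confusion, r2$confusion)
  expect_error(svm_crossval(d$x, d$y, folds = 13), "class smaller")
})

test_that("accuracy is invariant to feature order and affine rescaling", {
  d <- separable_classes(shift = 1.5)
  r <- svm_crossval(d$x, d$y, folds = 4, seed = 5)
  x_perm <- d$x[, c(3, 1, 5, 2, 4)]
  expect_equal(svm_crossval(x_perm, d$y, folds = 4, seed = 5)$accuracy,
               r$accuracy)
  x_scaled <- sweep(sweep(d$x, 2, c(2, 0.5, 10, 1, 3), "*"),
                    2, c(-4, 0, 7, 1, 0), "+")
  expect_equal(svm_crossval(x_scaled, d$y, folds = 4, seed = 5)$accuracy,
               r$accuracy)
})

test_that("permuted labels score at chance level", {
  d <- separable_classes()  # 4 balanced classes, chance = 25%
  accs <- vapply(1:20, function(s) {
    y_perm <- venose:::with_seed(s, sample(d$y))
    svm_crossval(d$x, y_perm, folds = 4, seed = s)$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 15)
  expect_lte(mean(accs), 35)
})

test_that("concentration levels within a gas classify as classes", {
  set.seed(31)
  conc <- rep(seq(250, 3000, length.out = 7), each = 6)
  x <- cbind(f1 = conc / 100 + rnorm(42, sd = 0.05),
             f2 = sqrt(conc) + rnorm(42, sd = 0.05))
  r <- per_gas_concentration_classifier(x, conc, folds = 6, seed = 1)
  expect_equal(nrow(r$confusion), 7)
  expect_equal(r$accuracy, 100)
  # two identical-distribution levels hover around 50%
  accs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    x2 <- matrix(rnorm(80), 40, 2)
    per_gas_concentration_classifier(x2, rep(c(100, 200), each = 20),
                                     folds = 4, seed = s)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 30)
  expect_lt(mean(accs), 70)
  expect_error(per_gas_concentration_classifier(x, rep(500, 42)),
               "2 concentration levels")
})

test_that("LDA projects onto classes-minus-one discriminant axes", {
  d <- separable_classes()
  proj <- lda_fit_project(d$x, d$y)
  expect_equal(setdiff(names(proj$scores), "label"),
               c("DF1", "DF2", "DF3"))
  expect_equal(proj$method, "lda")
  # discriminability is ordered: DF1 separates more than DF2
  bv <- function(col) {
    cm <- tapply(proj$scores[[col]], proj$scores$label, mean)
    var(as.numeric(cm))
  }
  expect_gt(bv("DF1"), bv("DF2"))
})

test_that("identical classes collapse to coinciding centroids", {
  set.seed(41)
  base <- matrix(rnorm(60), 30, 2)
  x <- rbind(base, base)  # class b duplicates class a exactly
  x <- x + rnorm(120, sd = 1e-8)
  y <- factor(rep(c("a", "b"), each = 30))
  proj <- lda_fit_project(x, y)
  cm <- tapply(proj$scores$DF1, proj$scores$label, mean)
  expect_equal(unname(diff(cm)), 0, tolerance = 1e-3)
})

test_that("singular within-class scatter falls back to shrinkage", {
  set.seed(43)
  x <- matrix(rnorm(8 * 20), 8, 20)  # p >> n forces singularity
  colnames(x) <- paste0("f", 1:20)
  y <- factor(rep(c("a", "b"), each = 4))
  expect_message(proj <- lda_fit_project(x, y), "shrinkage")
  expect_equal(proj$method, "shrinkage")
  expect_equal(ncol(proj$scores) - 1L, 1L)
})

test_that("PLS1 core agrees with least squares and mixOmics", {
  set.seed(51)
  x <- matrix(rnorm(30 * 6), 30, 6)
  colnames(x) <- paste0("f", 1:6)
  y <- drop(x %*% runif(6)) + rnorm(30, sd = 0.3)
  fit <- pls1_fit(x, y, ncomp = 6)
  # full-rank PLS reproduces OLS fitted values on the training data
  expect_equal(predict(fit, x), unname(fitted(lm(y ~ x))),
               tolerance = 1e-8)
  # component-wise agreement with the reference implementation
  ref <- mixOmics::pls(x, y, ncomp = 4, mode = "regression",
                       scale = FALSE)
  for (a in 1:4) {
    expect_equal(unname(predict(fit, x, ncomp = a)),
                 unname(predict(ref, x)$predict[, 1, a]),
                 tolerance = 1e-8)
  }
  expect_error(pls1_fit(x, y, ncomp = 0), "ncomp")
  expect_error(pls1_fit(x, y, ncomp = 40), "ncomp")
})

test_that("PLSR recovers a noiseless linear response", {
  set.seed(52)
  x <- matrix(rnorm(60 * 5), 60, 5)
  colnames(x) <- paste0("f", 1:5)
  y <- drop(x %*% c(3, -1, 2, 0.5, 1)) + 50
  q <- plsr_quantify(x, y, folds = 5, split_seed = 1)
  expect_gte(q$r2, 0.999)
  expect_lt(q$rmse, 1e-6 * sd(y))
  expect_equal(q$n_test + q$n_train, 60)
  expect_error(plsr_quantify(x, y, n_components = 50), "rank")
})

test_that("PLSR on permuted responses has no predictive power", {
  set.seed(53)
  x <- matrix(rnorm(60 * 5), 60, 5)
  colnames(x) <- paste0("f", 1:5)
  y <- drop(x %*% c(3, -1, 2, 0.5, 1))
  r2s <- vapply(1:20, function(s) {
    y_perm <- venose:::with_seed(s, sample(y))
    plsr_quantify(x, y_perm, n_components = 2, split_seed = s)$r2
  }, numeric(1))
  expect_lte(median(r2s), 0.1)
  expect_lte(mean(r2s > 0.5), 0.1)
})
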