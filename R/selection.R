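# Sequential forward selection with a cross-validated criterion.

# Cross-validated criterion of a fixed feature subset. Features are
# z-scored with parameters learned on each training fold only.
cv_score_subset <- function(x, y, cols, fold, criterion, kernel, ncomp_max) {
  folds <- max(fold)
  xs <- x[, cols, drop = FALSE]
  if (criterion == "plsr") {
    pred <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f
      zs <- zscore_fit(xs[tr, , drop = FALSE])
      xtr <- zscore_apply(xs[tr, , drop = FALSE], zs)
      xte <- zscore_apply(xs[!tr, , drop = FALSE], zs)
      nc <- min(ncomp_max, ncol(xtr), sum(tr) - 1L)
      fit <- pls1_fit(xtr, y[tr], nc)
      pred[!tr] <- predict(fit, xte)
    }
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)  # pooled out-of-fold R2
  } else {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) next
      zs <- zscore_fit(xs[tr, , drop = FALSE])
      xtr <- zscore_apply(xs[tr, , drop = FALSE], zs)
      xte <- zscore_apply(xs[!tr, , drop = FALSE], zs)
      fit <- svm_fit(xtr, factor(y[tr]), kernel)
      correct <- correct +
        sum(as.character(predict(fit, xte)) == as.character(y[!tr]))
    }
    correct / length(y)
  }
}

#' Sequential forward feature selection
#'
#' Plain greedy forward search: starting from the empty set, each step adds
#' the feature that maximizes the cross-validated criterion of the grown
#' subset; ties are broken towards the lowest column index. The fold
#' assignment is drawn once from `seed` and reused for every candidate, so
#' the search is deterministic given the seed. No backtracking or floating
#' steps.
#'
#' Criteria: `"svm"` (default for a factor `y`) scores a subset by the
#' pooled out-of-fold accuracy of a support vector machine; `"plsr"`
#' (default for numeric `y`) by the pooled out-of-fold R-squared of a PLS
#' regression. Features are z-scored inside each training fold.
#'
#' @param x Feature matrix or `venose_features` data frame (label columns
#'   are dropped automatically).
#' @param y Class labels (factor/character) or numeric response.
#' @param k Number of features to select.
#' @param criterion `"svm"` or `"plsr"` (default chosen from the type of
#'   `y`).
#' @param kernel SVM kernel for the `"svm"` criterion, see
#'   [svm_crossval()].
#' @param folds Number of cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @param ncomp_max Cap on PLS components inside the criterion.
#' @return Object of class `"sfs_result"`: `selected` (feature names, in
#'   inclusion order), `indices`, `scores` (criterion after each
#'   inclusion), `criterion`, `folds`, `seed`.
#' @export
sfs_select <- function(x, y, k = 8,
                       criterion = NULL,
                       kernel = c("quadratic", "linear"),
                       folds = 10, seed = 1,
                       ncomp_max = 3) {
  if (inherits(x, "venose_features")) x <- feature_xy(x)$x
  x <- as_feature_matrix(x)
  kernel <- match.arg(kernel)
  if (k <= 0) stop("k must be positive")
  if (k > ncol(x)) stop("k exceeds the number of features")
  if (is.null(criterion)) {
    criterion <- if (is.numeric(y)) "plsr" else "svm"
  }
  criterion <- match.arg(criterion, c("svm", "plsr"))
  if (criterion == "svm") {
    y <- factor(y)
    if (nlevels(y) < 2L) stop("classification needs at least 2 classes")
  } else {
    y <- as.numeric(y)
  }
  fold <- stratified_folds(y, folds, seed)

  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(ncol(x))
  for (step in seq_len(k)) {
    cand_scores <- vapply(remaining, function(j) {
      cv_score_subset(x, y, c(selected, j), fold, criterion, kernel,
                      ncomp_max)
    }, numeric(1))
    best <- remaining[which.max(cand_scores)]  # which.max -> lowest index
    selected <- c(selected, best)
    scores <- c(scores, max(cand_scores))
    remaining <- setdiff(remaining, best)
  }
  structure(list(selected = colnames(x)[selected], indices = selected,
                 scores = scores, criterion = criterion, kernel = kernel,
                 folds = folds, seed = seed),
            class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat("Sequential forward selection (", x$criterion, " criterion, ",
      x$folds, "-fold CV)\n", sep = "")
  for (i in seq_along(x$selected)) {
    cat(sprintf("  %2d. %-10s score %.4f\n", i, x$selected[i],
                x$scores[i]))
  }
  invisible(x)
}
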