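# Evaluation heads: LDA projection, cross-validated SVM classification,
# and PLSR concentration calibration with RMSE / R-squared metrics.

# e1071 SVM with the two kernels used here; features are assumed z-scored.
svm_fit <- function(x, y, kernel = c("quadratic", "linear"), cost = 1) {
  kernel <- match.arg(kernel)
  if (kernel == "quadratic") {
    e1071::svm(x, y, kernel = "polynomial", degree = 2, coef0 = 1,
               cost = cost, scale = FALSE)
  } else {
    e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  }
}

#' Error metrics for quantification
#'
#' Root mean square error and coefficient of determination
#' R2 = 1 - SS_res / SS_tot. Predicting the mean of the truth gives
#' R2 = 0; R2 is negative when predictions are worse than that.
#'
#' @param true Numeric vector of reference values (length >= 2, non-zero
#'   variance).
#' @param predicted Numeric vector of predictions.
#' @return List with elements `rmse` and `r2`.
#' @examples
#' compute_metrics(c(0, 1, 2), c(0, 1, 5))  # rmse sqrt(3), r2 -3.5
#' @export
compute_metrics <- function(true, predicted) {
  if (length(true) != length(predicted)) stop("length mismatch")
  if (length(true) < 2L) stop("need at least 2 observations")
  ss_tot <- sum((true - mean(true))^2)
  if (ss_tot == 0) stop("R2 undefined for zero-variance truth")
  ss_res <- sum((true - predicted)^2)
  list(rmse = sqrt(mean((true - predicted)^2)), r2 = 1 - ss_res / ss_tot)
}

#' Cross-validated SVM classification
#'
#' Stratified k-fold cross-validation of a support vector machine
#' (one-vs-one multi-class, as implemented in e1071). Out-of-fold
#' predictions populate the confusion matrix; features are z-scored with
#' parameters learned on each training fold only.
#'
#' @param x Feature matrix or `venose_features` data frame.
#' @param y Class labels (factor or character); for the gas-identity task
#'   each gas forms one group pooling all its concentrations.
#' @param kernel `"quadratic"` (polynomial degree 2) or `"linear"`.
#' @param folds Number of folds; every class must have at least `folds`
#'   members.
#' @param seed Seed for the fold assignment.
#' @param cost SVM cost parameter.
#' @return Object of class `"venose_classification"`: `confusion` (counts,
#'   true x predicted), `confusion_pct` (row percentages), `class_rate`
#'   (per-class correct-classification rate, percent), `accuracy`
#'   (overall validation accuracy, percent), `predicted`, plus kernel /
#'   fold metadata.
#' @export
svm_crossval <- function(x, y, kernel = c("quadratic", "linear"),
                         folds = 10, seed = 1, cost = 1) {
  if (inherits(x, "venose_features")) x <- feature_xy(x)$x
  x <- as_feature_matrix(x)
  kernel <- match.arg(kernel)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  counts <- table(y)
  if (any(counts < folds)) {
    stop("class smaller than fold count: ",
         paste(names(counts)[counts < folds], collapse = ", "))
  }
  fold <- stratified_folds(y, folds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    zs <- zscore_fit(x[tr, , drop = FALSE])
    fit <- svm_fit(zscore_apply(x[tr, , drop = FALSE], zs),
                   droplevels(y[tr]), kernel, cost)
    p <- predict(fit, zscore_apply(x[!tr, , drop = FALSE], zs))
    pred[!tr] <- as.character(p)
  }
  confusion <- table(true = y, predicted = pred)
  class_rate <- 100 * diag(confusion) / rowSums(confusion)
  structure(list(
    confusion = confusion,
    confusion_pct = 100 * prop.table(confusion, margin = 1),
    class_rate = class_rate,
    accuracy = 100 * sum(diag(confusion)) / length(y),
    predicted = pred, truth = y,
    kernel = kernel, folds = folds, seed = seed
  ), class = "venose_classification")
}

#' @export
print.venose_classification <- function(x, ...) {
  cat(sprintf("%d-fold CV %s SVM: validation accuracy %.1f%%\n",
              x$folds, x$kernel, x$accuracy))
  cat("Confusion matrix (counts):\n")
  print(x$confusion)
  cat("Per-class correct-classification rate (%):\n")
  print(round(x$class_rate, 1))
  invisible(x)
}

#' Concentration-level classification within one gas
#'
#' Treats each concentration level of a single gas as a class and runs the
#' same stratified cross-validated SVM as [svm_crossval()].
#'
#' @param x Feature matrix for the cycles of one gas.
#' @param conc_ppb Concentrations in ppb (each distinct value = one class).
#' @param ... Passed to [svm_crossval()] (`kernel`, `folds`, `seed`, ...).
#' @return A `venose_classification` whose classes are the concentration
#'   levels.
#' @export
per_gas_concentration_classifier <- function(x, conc_ppb, ...) {
  lev <- sort(unique(conc_ppb))
  if (length(lev) < 2L) stop("need at least 2 concentration levels")
  y <- factor(conc_ppb, levels = lev)
  svm_crossval(x, y, ...)
}

#' Linear discriminant projection
#'
#' Z-scores the features and projects the observations onto the linear
#' discriminant functions (at most one fewer than the number of classes),
#' for visual assessment of class separation. If the within-class scatter
#' is singular (as with more features than the smallest class supports),
#' a shrinkage fallback regularizes the within-class covariance towards a
#' scaled identity and solves the generalized eigenproblem directly; a
#' message notes the fallback.
#'
#' @param x Feature matrix or `venose_features` data frame.
#' @param y Class labels.
#' @param shrink Shrinkage weight used only by the fallback path.
#' @return Object of class `"venose_lda"`: `scores` (data frame DF1..DFd +
#'   `label`), `explained` (proportion of discriminability per axis) and
#'   `method` (`"lda"` or `"shrinkage"`).
#' @export
lda_fit_project <- function(x, y, shrink = 0.1) {
  if (inherits(x, "venose_features")) x <- feature_xy(x)$x
  x <- as_feature_matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  zs <- zscore_fit(x)
  xz <- zscore_apply(x, zs)
  d <- min(nlevels(y) - 1L, ncol(xz))

  # collinear predictors mean a singular within-class scatter: treat
  # MASS's collinearity warning like the singular-scatter error
  fit <- tryCatch(
    withCallingHandlers(
      MASS::lda(xz, grouping = y),
      warning = function(w) stop(conditionMessage(w))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    proj <- predict(fit, xz)$x[, seq_len(d), drop = FALSE]
    svd_prop <- fit$svd^2 / sum(fit$svd^2)
    method <- "lda"
  } else {
    message("within-class scatter singular; using shrinkage LDA fallback")
    # pooled within-class and between-class scatter
    p <- ncol(xz)
    w <- matrix(0, p, p); b <- matrix(0, p, p)
    mu <- colMeans(xz)
    for (cl in levels(y)) {
      xc <- xz[y == cl, , drop = FALSE]
      cc <- sweep(xc, 2, colMeans(xc))
      w <- w + crossprod(cc)
      b <- b + nrow(xc) * tcrossprod(colMeans(xc) - mu)
    }
    w <- (1 - shrink) * w + shrink * mean(diag(w)) * diag(p)
    eg <- eigen(solve(w, b))
    ord <- order(Re(eg$values), decreasing = TRUE)[seq_len(d)]
    vec <- Re(eg$vectors[, ord, drop = FALSE])
    proj <- xz %*% vec
    ev <- Re(eg$values[ord])
    svd_prop <- ev / sum(ev)
    method <- "shrinkage"
  }
  colnames(proj) <- paste0("DF", seq_len(d))
  structure(list(
    scores = data.frame(proj, label = y),
    explained = svd_prop[seq_len(d)],
    method = method
  ), class = "venose_lda")
}

#' @export
print.venose_lda <- function(x, ...) {
  d <- ncol(x$scores) - 1L
  cat("LDA projection onto", d, "discriminant function(s);",
      "discriminability proportions:",
      paste(sprintf("%.2f", x$explained), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.venose_lda <- function(x, dims = c(1, 2), ...) {
  s <- x$scores
  d <- ncol(s) - 1L
  if (d == 1L) {
    graphics::stripchart(s$DF1 ~ s$label, vertical = TRUE, pch = 19,
                         method = "jitter", xlab = "", ylab = "DF1", ...)
  } else {
    dims <- pmin(dims, d)
    cols <- as.integer(s$label)
    graphics::plot(s[[dims[1]]], s[[dims[2]]], col = cols,
                   pch = cols, xlab = paste0("DF", dims[1]),
                   ylab = paste0("DF", dims[2]), ...)
    graphics::legend("topright", legend = levels(s$label),
                     col = seq_len(nlevels(s$label)),
                     pch = seq_len(nlevels(s$label)), bty = "n")
  }
  invisible(x)
}

#' PLSR concentration calibration
#'
#' Partial least squares regression of concentration on the features.
#' The data are split once into a training set (80% by default, stratified
#' over concentration levels) and a held-out test set, before any fitting;
#' z-scoring parameters and the number of latent components are learned on
#' the training set only. Components are chosen by k-fold cross-validation
#' on the training set: the smallest number of components whose CV RMSE is
#' within one standard error of the minimum. Reported R2 / RMSE are
#' computed on the held-out test set.
#'
#' @param x Feature matrix or `venose_features` data frame.
#' @param y Concentrations in ppb.
#' @param n_components Number of latent components; `NULL` (default) =
#'   choose by cross-validation.
#' @param folds CV folds for component selection.
#' @param split_seed Seed for the train/test split (and CV folds).
#' @param test_fraction Held-out fraction.
#' @param ncomp_max Largest number of components considered.
#' @return Object of class `"venose_quantification"`: `predicted` / `true`
#'   (test set, ppb), `r2`, `rmse`, `ncomp`, `n_train`, `n_test`,
#'   `cv_rmse` (per candidate component count) and the fitted `model`
#'   (z-scoring parameters + [pls1_fit()] on the training set).
#' @export
plsr_quantify <- function(x, y, n_components = NULL, folds = 10,
                          split_seed = 1, test_fraction = 0.2,
                          ncomp_max = 10) {
  if (inherits(x, "venose_features")) x <- feature_xy(x)$x
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(x) != n) stop("x and y sizes differ")

  # split stratified over concentration levels when levels are replicated;
  # a plain random split otherwise (essentially continuous response)
  lev <- factor(y)
  test <- logical(n)
  with_seed(split_seed, {
    if (min(table(lev)) >= 3L) {
      for (cl in levels(lev)) {
        idx <- which(lev == cl)
        n_test <- max(1L, round(length(idx) * test_fraction))
        test[sample(idx, n_test)] <- TRUE
      }
    } else {
      test[sample.int(n, max(1L, round(n * test_fraction)))] <- TRUE
    }
  })
  xtr <- x[!test, , drop = FALSE]; ytr <- y[!test]
  xte <- x[test, , drop = FALSE];  yte <- y[test]

  zs <- zscore_fit(xtr)
  xtr_z <- zscore_apply(xtr, zs)
  xte_z <- zscore_apply(xte, zs)

  nc_cap <- min(ncomp_max, ncol(x), nrow(xtr) - 2L)
  if (nc_cap < 1) stop("too few training observations for PLSR")
  cv_rmse <- NULL
  if (is.null(n_components)) {
    fold_by <- if (min(table(factor(ytr))) >= 3L) factor(ytr) else ytr
    fold <- stratified_folds(fold_by, min(folds, nrow(xtr)),
                             split_seed + 1)
    nfold <- max(fold)
    err <- matrix(NA_real_, nfold, nc_cap)  # fold x ncomp squared errors
    for (f in seq_len(nfold)) {
      tr <- fold != f
      ncf <- min(nc_cap, sum(tr) - 1L)
      zsf <- zscore_fit(xtr[tr, , drop = FALSE])
      fit <- pls1_fit(zscore_apply(xtr[tr, , drop = FALSE], zsf),
                      ytr[tr], ncf)
      xv <- zscore_apply(xtr[!tr, , drop = FALSE], zsf)
      for (a in seq_len(ncf)) {
        err[f, a] <- sqrt(mean((ytr[!tr] - predict(fit, xv, a))^2))
      }
    }
    cv_rmse <- colMeans(err, na.rm = TRUE)
    cv_se <- apply(err, 2, function(e) {
      sd(e, na.rm = TRUE) / sqrt(sum(!is.na(e)))
    })
    best <- which.min(cv_rmse)
    n_components <-
      min(which(cv_rmse <= cv_rmse[best] + cv_se[best]))  # 1-SE rule
  }
  if (n_components >= min(nrow(xtr), ncol(x) + 1L)) {
    stop("n_components must be below the rank of the training features")
  }
  fit <- pls1_fit(xtr_z, ytr, n_components)
  pred <- predict(fit, xte_z)
  met <- compute_metrics(yte, pred)
  structure(list(
    predicted = pred, true = yte,
    r2 = met$r2, rmse = met$rmse, ncomp = n_components,
    n_train = nrow(xtr), n_test = nrow(xte), cv_rmse = cv_rmse,
    model = list(zscore = zs, fit = fit),
    split_seed = split_seed
  ), class = "venose_quantification")
}

#' @export
print.venose_quantification <- function(x, ...) {
  cat(sprintf(
    "PLSR calibration: %d component(s), train n=%d, test n=%d\n",
    x$ncomp, x$n_train, x$n_test))
  cat(sprintf("  test R2 = %.3f, RMSE = %.0f ppb\n", x$r2, x$rmse))
  invisible(x)
}

#' @export
plot.venose_quantification <- function(x, ...) {
  rng <- range(c(x$true, x$predicted))
  graphics::plot(x$true, x$predicted, xlim = rng, ylim = rng,
                 xlab = "true concentration (ppb)",
                 ylab = "predicted concentration (ppb)", pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
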