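# The central fit: feature selection + the three evaluation heads, wrapped
# in one classed object.

#' Fit the virtual electronic nose analysis
#'
#' Runs the full chemometric analysis on a per-cycle feature table:
#' sequential forward selection of `k` features for the gas-identity task,
#' cross-validated SVM classification of gas identity (each gas one group,
#' pooling all its concentrations), an LDA projection of the selected
#' features, and, per gas, concentration-level classification and PLSR
#' concentration calibration, each with its own forward selection.
#'
#' For the per-gas concentration classifier the fold count is capped at
#' the smallest concentration-level class so a stratified CV remains
#' possible at desk scale (a handful of cycles per level); the
#' gas-identity task keeps the full fold count.
#'
#' @param features A `venose_features` table from [extract_features()].
#' @param k Number of features selected per task.
#' @param kernel SVM kernel: `"quadratic"` (default) or `"linear"`.
#' @param folds Cross-validation folds.
#' @param seed Master seed for fold assignments and splits.
#' @param quantify_gases Gases to calibrate (default: all non-SA gases
#'   present).
#' @return Object of class `"venose"` with components `selection`
#'   ([sfs_select()] result), `classification`
#'   ([svm_crossval()] report), `lda` ([lda_fit_project()] scores),
#'   `concentration` and `quantification` (per-gas lists), and the final
#'   full-data gas classifier used by [predict.venose()].
#' @examples
#' \donttest{
#' study <- make_fixtures("tiny")
#' fit <- venose(extract_features(study_observations(study, discard = 1)),
#'               k = 3, folds = 4, seed = 1)
#' print(fit)
#' }
#' @export
venose <- function(features, k = 8, kernel = c("quadratic", "linear"),
                   folds = 10, seed = 1,
                   quantify_gases = NULL) {
  stopifnot(inherits(features, "venose_features"))
  kernel <- match.arg(kernel)
  xy <- feature_xy(features)
  seeds <- child_seeds(seed, 4L)

  sel <- sfs_select(xy$x, xy$gas, k = k, criterion = "svm",
                    kernel = kernel, folds = folds, seed = seeds[1])
  x_sel <- xy$x[, sel$indices, drop = FALSE]

  gas_report <- svm_crossval(x_sel, xy$gas, kernel = kernel,
                             folds = folds, seed = seeds[2])
  lda <- lda_fit_project(x_sel, xy$gas)

  if (is.null(quantify_gases)) {
    quantify_gases <- setdiff(levels(xy$gas), "SA")
  }
  concentration <- list()
  quantification <- list()
  for (g in quantify_gases) {
    rows <- xy$gas == g
    xg <- xy$x[rows, , drop = FALSE]
    cg <- xy$conc_ppb[rows]
    lev_n <- min(table(cg))
    fg <- min(folds, lev_n)
    sel_c <- sfs_select(xg, factor(cg), k = k, criterion = "svm",
                        kernel = kernel, folds = fg, seed = seeds[3])
    concentration[[g]] <- list(
      selection = sel_c,
      report = per_gas_concentration_classifier(
        xg[, sel_c$indices, drop = FALSE], cg,
        kernel = kernel, folds = fg, seed = seeds[3]))
    sel_q <- sfs_select(xg, cg, k = k, criterion = "plsr",
                        folds = folds, seed = seeds[4])
    quantification[[g]] <- list(
      selection = sel_q,
      report = plsr_quantify(xg[, sel_q$indices, drop = FALSE], cg,
                             folds = folds, split_seed = seeds[4]))
  }

  # final gas classifier on all observations, for predict()
  zs <- zscore_fit(x_sel)
  final_svm <- svm_fit(zscore_apply(x_sel, zs), xy$gas, kernel)

  structure(list(
    selection = sel,
    classification = gas_report,
    lda = lda,
    concentration = concentration,
    quantification = quantification,
    final = list(zscore = zs, svm = final_svm, features = sel$selected),
    k = k, kernel = kernel, folds = folds, seed = seed,
    n_obs = nrow(xy$x),
    call = match.call()
  ), class = "venose")
}

#' @export
print.venose <- function(x, ...) {
  cat("Virtual electronic nose fit\n")
  cat(sprintf("  %d observations, %d selected features (%s)\n",
              x$n_obs, x$k, paste(x$selection$selected, collapse = ", ")))
  cat(sprintf("  gas identity: %d-fold CV %s SVM accuracy %.1f%%\n",
              x$folds, x$kernel, x$classification$accuracy))
  for (g in names(x$quantification)) {
    q <- x$quantification[[g]]$report
    cr <- x$concentration[[g]]$report
    cat(sprintf("  %-8s conc. classification %.1f%%, PLSR R2 %.3f (RMSE %.0f ppb)\n",
                g, cr$accuracy, q$r2, q$rmse))
  }
  invisible(x)
}

#' @export
summary.venose <- function(object, ...) {
  print(object)
  cat("\nPer-class correct-classification rate (%):\n")
  print(round(object$classification$class_rate, 1))
  cat("\nConfusion matrix (gas identity, counts):\n")
  print(object$classification$confusion)
  cat("\nSelection score path:\n")
  print(object$selection)
  invisible(object)
}

#' @export
plot.venose <- function(x, ...) {
  plot(x$lda, main = "LDA of selected features", ...)
  invisible(x)
}

#' Predict gas identity and concentration for new cycles
#'
#' Classifies each observation with the full-data SVM on the selected
#' features, then predicts the concentration with the corresponding
#' per-gas PLSR calibration (NA when the predicted class has no
#' calibration, e.g. synthetic air).
#'
#' @param object A fitted [venose()] model.
#' @param newdata A `venose_features` table or feature matrix with the
#'   full catalog columns.
#' @param ... Unused.
#' @return Data frame with columns `gas` (predicted identity) and
#'   `conc_ppb` (predicted concentration).
#' @export
predict.venose <- function(object, newdata, ...) {
  if (inherits(newdata, "venose_features")) {
    newdata <- feature_xy(newdata)$x
  }
  newdata <- as_feature_matrix(newdata)
  x_sel <- newdata[, object$final$features, drop = FALSE]
  gas <- predict(object$final$svm,
                 zscore_apply(x_sel, object$final$zscore))
  conc <- rep(NA_real_, nrow(newdata))
  for (g in names(object$quantification)) {
    rows <- gas == g
    if (!any(rows)) next
    q <- object$quantification[[g]]
    xq <- newdata[rows, q$selection$selected, drop = FALSE]
    conc[rows] <- predict(q$report$model$fit,
                          zscore_apply(xq, q$report$model$zscore))
  }
  data.frame(gas = as.character(gas), conc_ppb = conc,
             stringsAsFactors = FALSE)
}
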