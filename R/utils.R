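# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft lm predict rnorm sd var coef
#' @importFrom utils head read.csv tail write.csv
NULL

GASES <- c("SA", "CH2O", "CH2O2", "CH3COOH")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so seeded helpers do not perturb each other.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive n child seeds (< 2^31) from a master seed.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Stratified fold assignment. Factor y: round-robin within each class after
# a seeded shuffle, so every class is spread over folds as evenly as its
# size allows. Numeric y: plain seeded shuffle dealt round-robin.
stratified_folds <- function(y, folds, seed) {
  stopifnot(folds >= 2)
  n <- length(y)
  fold <- integer(n)
  with_seed(seed, {
    if (is.factor(y) || is.character(y)) {
      y <- as.factor(y)
      for (cl in levels(y)) {
        idx <- which(y == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(seq_len(folds), length(idx))
      }
    } else {
      ord <- order(y)[sample.int(n)]  # shuffle; order() only to break ties
      idx <- sample.int(n)
      fold[idx] <- rep_len(seq_len(folds), n)
    }
  })
  fold
}

# Column-wise z-scoring with parameters learned on the training rows only.
# Constant columns keep sd 1 so they map to exact zeros rather than NaN.
zscore_fit <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}

zscore_apply <- function(x, zs) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, zs$mean, "-"), 2, zs$sd, "/")
}

as_feature_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) {
    stop("feature matrix contains missing or non-finite values")
  }
  x
}
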