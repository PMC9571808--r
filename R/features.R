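# The 299-dimensional per-cycle feature catalog: windowed means, windowed
# OLS slopes, windowed FFT magnitudes, cycle integral and lifting.

#' Feature catalog for a temperature program
#'
#' Enumerates the per-cycle features and their sample windows. For the
#' default program (1100 samples at 10 Hz) the catalog is 55 means over
#' 2 s windows, 220 slopes over 0.5 s windows, 22 FFT magnitudes over 5 s
#' windows, one integral and one lifting: 299 features. Windows within a
#' family are contiguous, non-overlapping, 0-based half-open, and tile the
#' cycle exactly; counts scale as cycle duration / window for other
#' programs.
#'
#' @param program A [temperature_program()].
#' @param mean_window_s,slope_window_s,fft_window_s Window lengths in
#'   seconds for the three windowed families.
#' @param fft_bin Which non-negative DFT bin magnitude summarizes each FFT
#'   window; default 1, the first non-DC coefficient (the DC bin would
#'   duplicate the windowed means).
#' @return A data frame of class `"feature_catalog"` with columns
#'   `name, family, start, end` (half-open sample windows; `NA` for the
#'   whole-cycle integral and lifting), plus attributes for the window
#'   sizes and `fft_bin`.
#' @examples
#' nrow(feature_catalog(temperature_program()))  # 299
#' @export
feature_catalog <- function(program = temperature_program(),
                            mean_window_s = 2,
                            slope_window_s = 0.5,
                            fft_window_s = 5,
                            fft_bin = 1) {
  n <- program$cycle_samples
  rate <- program$sampling_rate
  wins <- function(window_s, prefix, digits) {
    w <- window_s * rate
    if (abs(w - round(w)) > 1e-9) stop("window must be whole samples")
    w <- as.integer(round(w))
    if (n %% w != 0) {
      stop("cycle length ", n, " not divisible by ", prefix,
           " window of ", w, " samples")
    }
    k <- n %/% w
    data.frame(
      name = sprintf(paste0(prefix, "_%0", digits, "d"), seq_len(k)),
      family = prefix,
      start = (seq_len(k) - 1L) * w,
      end = seq_len(k) * w,
      stringsAsFactors = FALSE)
  }
  cat_df <- rbind(
    wins(mean_window_s, "mean", 2),
    wins(slope_window_s, "slope", 3),
    wins(fft_window_s, "fft", 2),
    data.frame(name = "integral", family = "integral",
               start = NA_integer_, end = NA_integer_),
    data.frame(name = "lifting", family = "lifting",
               start = NA_integer_, end = NA_integer_)
  )
  if (fft_bin < 1) stop("fft_bin must be >= 1")
  structure(cat_df, class = c("feature_catalog", "data.frame"),
            program = program, fft_bin = as.integer(fft_bin),
            mean_window = as.integer(mean_window_s * rate),
            slope_window = as.integer(slope_window_s * rate),
            fft_window = as.integer(fft_window_s * rate))
}

# rows of Y restricted to one family's windows, as cycles x windows blocks
window_apply <- function(y, w, fun) {
  n <- length(y)
  k <- n %/% w
  m <- matrix(y[seq_len(k * w)], nrow = w)
  apply(m, 2, fun)
}

#' Windowed means of a cycle
#'
#' Arithmetic mean of the cycle over consecutive non-overlapping windows
#' (default 2 s = 20 samples; 55 values for the default program).
#'
#' @param cycle Numeric vector (one cycle, normally standardized).
#' @param window Window length in samples.
#' @return Numeric vector of one mean per window.
#' @export
windowed_means <- function(cycle, window = 20L) {
  n <- length(cycle)
  if (n %% window != 0) stop("cycle length not divisible by window size")
  colMeans(matrix(cycle, nrow = window))
}

#' Windowed OLS slopes of a cycle
#'
#' Ordinary-least-squares slope of signal vs time over consecutive windows
#' (default 0.5 s = 5 samples; 220 values for the default program), in
#' signal units per second.
#'
#' @param cycle Numeric vector.
#' @param window Window length in samples.
#' @param dt Sampling interval in seconds.
#' @return Numeric vector of one slope per window.
#' @export
windowed_slopes <- function(cycle, window = 5L, dt = 0.1) {
  n <- length(cycle)
  if (n %% window != 0) stop("cycle length not divisible by window size")
  t <- (seq_len(window) - 1) * dt
  tc <- t - mean(t)
  wvec <- tc / sum(tc^2)  # closed-form OLS slope weights
  as.numeric(crossprod(matrix(cycle, nrow = window), wvec))
}

#' Windowed FFT magnitudes of a cycle
#'
#' Magnitude of one discrete-Fourier coefficient (unnormalized transform)
#' of each consecutive window (default 5 s = 50 samples; 22 values for the
#' default program). By default the first non-DC bin: a sinusoid of
#' amplitude a with exactly one period per 50-sample window yields 25a.
#'
#' @param cycle Numeric vector.
#' @param window Window length in samples.
#' @param bin DFT bin index (1 = first non-DC coefficient).
#' @return Numeric vector of one magnitude per window.
#' @export
windowed_ffts <- function(cycle, window = 50L, bin = 1L) {
  n <- length(cycle)
  if (n %% window != 0) stop("cycle length not divisible by window size")
  if (bin < 1 || bin >= window) stop("bin must be in [1, window)")
  m <- matrix(cycle, nrow = window)
  abs(stats::mvfft(m)[bin + 1L, ])
}

#' Cycle integral
#'
#' Trapezoidal integral of the cycle signal against time
#' (signal-units x seconds).
#'
#' @param cycle Numeric vector.
#' @param dt Sampling interval in seconds.
#' @return Scalar integral.
#' @export
cycle_integral <- function(cycle, dt = 0.1) {
  n <- length(cycle)
  dt * (sum(cycle) - (cycle[1] + cycle[n]) / 2)
}

#' Cycle lifting
#'
#' Difference between the last and first sample of a cycle (positive
#' lifting = the cycle ends higher than it starts).
#'
#' @param cycle Numeric vector.
#' @return Scalar lifting.
#' @export
lifting <- function(cycle) {
  cycle[length(cycle)] - cycle[1]
}

#' Extract the full feature matrix from cycles
#'
#' Evaluates the whole [feature_catalog()] on every cycle and assembles the
#' observation x feature matrix with gas / concentration labels.
#'
#' @param cycles A standardized `cycle_set` (a plain numeric matrix of
#'   cycles in rows is also accepted).
#' @param catalog A [feature_catalog()] matching the cycles' program.
#' @return A data frame of class `"venose_features"`: columns `gas`,
#'   `conc_ppb` then one column per catalog feature, rows in cycle order.
#'   The catalog travels along as attribute `"catalog"`.
#' @export
extract_features <- function(cycles, catalog = NULL) {
  if (inherits(cycles, "cycle_set")) {
    if (is.null(catalog)) catalog <- feature_catalog(cycles$program)
    sig <- cycles$signal
    meta <- cycles$meta
  } else {
    sig <- as.matrix(cycles)
    if (is.null(catalog)) {
      stop("catalog must be supplied for a bare cycle matrix")
    }
    meta <- data.frame(gas = NA_character_, conc_ppb = NA_real_,
                       stringsAsFactors = FALSE)[rep(1, nrow(sig)), ]
  }
  program <- attr(catalog, "program")
  if (ncol(sig) != program$cycle_samples) {
    stop("cycle length does not match the catalog's program")
  }
  dt <- 1 / program$sampling_rate
  mw <- attr(catalog, "mean_window")
  sw <- attr(catalog, "slope_window")
  fw <- attr(catalog, "fft_window")
  fb <- attr(catalog, "fft_bin")

  feat <- t(apply(sig, 1, function(y) {
    c(windowed_means(y, mw),
      windowed_slopes(y, sw, dt),
      windowed_ffts(y, fw, fb),
      cycle_integral(y, dt),
      lifting(y))
  }))
  colnames(feat) <- catalog$name
  if (anyNA(feat) || any(!is.finite(feat))) {
    stop("non-finite feature values")
  }
  out <- data.frame(gas = meta$gas, conc_ppb = meta$conc_ppb,
                    feat, check.names = FALSE, stringsAsFactors = FALSE)
  structure(out, class = c("venose_features", "data.frame"),
            catalog = catalog)
}

#' Split a feature table into matrix and labels
#'
#' @param features A `venose_features` data frame.
#' @return List with `x` (numeric matrix of features), `gas` (factor) and
#'   `conc_ppb` (numeric).
#' @export
feature_xy <- function(features) {
  stopifnot(inherits(features, "venose_features"))
  fcols <- setdiff(names(features), c("gas", "conc_ppb"))
  list(x = as_feature_matrix(features[fcols]),
       gas = factor(features$gas),
       conc_ppb = features$conc_ppb)
}
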