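# Cycle segmentation, smoothing, per-cycle auto-scaling, relative response
# and virtual-sensor construction.

#' Split a trace into temperature cycles
#'
#' Cuts a trace into consecutive whole cycles of
#' `program$cycle_samples` samples; a trailing partial cycle is discarded.
#' Each cycle is tagged with the dominant gas/concentration of its span and
#' a phase among `baseline` (carrier gas before the first exposure sample),
#' `exposure` (tagged iff at least 50% of the cycle's samples lie in a gas
#' segment) and `recovery` (carrier gas after exposure); remaining ties are
#' broken towards the later phase.
#'
#' @param trace A `sensor_trace` (the simulator guarantees that traces
#'   start on a cycle boundary).
#' @param program The [temperature_program()] that generated the trace.
#' @return An object of class `"cycle_set"`: list with `signal` (matrix,
#'   cycles x cycle_samples), `meta` (`cycle_idx, gas, conc_ppb, phase`),
#'   the `program`, and a `standardized` flag.
#' @export
segment_cycles <- function(trace, program = attr(trace, "program")) {
  if (is.null(program)) {
    stop("program must be supplied for traces without a program attribute")
  }
  n <- program$cycle_samples
  len <- nrow(trace)
  if (len < n) stop("trace shorter than one cycle")
  n_cyc <- len %/% n
  used <- n_cyc * n

  sig <- matrix(trace$current[seq_len(used)], nrow = n_cyc, ncol = n,
                byrow = TRUE)

  gas <- as.character(trace$gas[seq_len(used)])
  conc <- trace$conc_ppb[seq_len(used)]
  exposure_sample <- gas != "SA"
  first_on <- if (any(exposure_sample)) which(exposure_sample)[1] else Inf
  # per-sample phase under the single-exposure protocol
  phase_s <- ifelse(exposure_sample, "exposure",
                    ifelse(seq_len(used) < first_on, "baseline", "recovery"))

  cyc_of <- rep(seq_len(n_cyc), each = n)
  meta <- data.frame(cycle_idx = seq_len(n_cyc), gas = "SA", conc_ppb = 0,
                     phase = "baseline", stringsAsFactors = FALSE)
  phase_order <- c("baseline", "exposure", "recovery")
  for (i in seq_len(n_cyc)) {
    sel <- cyc_of == i
    n_exp <- sum(exposure_sample[sel])
    if (n_exp >= n / 2) {
      meta$phase[i] <- "exposure"
      gg <- gas[sel][exposure_sample[sel]]
      tab <- table(gg)
      meta$gas[i] <- names(tab)[which.max(tab)]
      meta$conc_ppb[i] <- max(conc[sel][gg == meta$gas[i]])
    } else {
      counts <- vapply(phase_order, function(p) sum(phase_s[sel] == p), 0L)
      # tie towards the later phase
      meta$phase[i] <- phase_order[max(which(counts == max(counts)))]
    }
  }
  structure(list(signal = sig, meta = meta, program = program,
                 standardized = FALSE),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(nrow(x$signal), "cycles x", ncol(x$signal), "samples",
      if (x$standardized) "(standardized)" else "(raw)", "\n")
  print(table(x$meta$gas, x$meta$phase))
  invisible(x)
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing with [signal::sgolayfilt()].
#' Polynomials of degree at most `polyorder` pass through unchanged.
#' Applies per cycle for a `cycle_set`, to the current channel for a
#' `sensor_trace`, and directly to a numeric vector.
#'
#' @param x Numeric vector, `sensor_trace` or `cycle_set`.
#' @param window_length Odd window length in samples (default 11 = 1.1 s
#'   at 10 Hz).
#' @param polyorder Polynomial order (< window_length).
#' @return Object of the same shape as `x`.
#' @export
sg_smooth <- function(x, window_length = 11, polyorder = 3) {
  if (window_length %% 2 == 0) stop("window_length must be odd")
  if (polyorder >= window_length) stop("polyorder must be < window_length")
  smooth1 <- function(v) {
    if (window_length > length(v)) stop("window longer than signal")
    signal::sgolayfilt(v, p = polyorder, n = window_length)
  }
  if (inherits(x, "cycle_set")) {
    x$signal <- t(apply(x$signal, 1, smooth1))
    x
  } else if (inherits(x, "sensor_trace")) {
    x$current <- smooth1(x$current)
    x
  } else {
    smooth1(as.numeric(x))
  }
}

#' Per-cycle auto-scaling
#'
#' Standardizes one cycle to zero mean and sample standard deviation 100:
#' y_std = (y - mean(y)) / sd(y) * 100 with the (n-1)-denominator sample
#' standard deviation. Removes additive baseline offsets and multiplicative
#' gain exactly (affine invariance), which is why it suppresses drift.
#'
#' @param y Numeric vector (one raw cycle).
#' @return Standardized numeric vector.
#' @examples
#' autoscale_cycle(c(1, 2, 3))  # -100 0 100
#' @export
autoscale_cycle <- function(y) {
  y <- as.numeric(y)
  s <- sd(y)
  if (!is.finite(s) || s == 0) {
    stop("cannot auto-scale a constant cycle (zero standard deviation)")
  }
  (y - mean(y)) / s * 100
}

#' @describeIn autoscale_cycle Auto-scale every cycle of a `cycle_set`;
#'   records the raw per-cycle means and sds in `meta`.
#' @param cycles A `cycle_set`.
#' @export
autoscale_cycles <- function(cycles) {
  stopifnot(inherits(cycles, "cycle_set"))
  mu <- rowMeans(cycles$signal)
  sdv <- apply(cycles$signal, 1, sd)
  if (any(!is.finite(sdv) | sdv == 0)) {
    stop("cannot auto-scale a constant cycle (zero standard deviation)")
  }
  cycles$meta$raw_mean <- mu
  cycles$meta$raw_sd <- sdv
  cycles$signal <- (cycles$signal - mu) / sdv * 100
  cycles$standardized <- TRUE
  cycles
}

#' Relative response
#'
#' Percent change of the sensor current under gas relative to carrier gas:
#' |I_air - I_gas| / I_air x 100. Vectorized.
#'
#' @param i_air Current under synthetic air (> 0).
#' @param i_gas Current under the target gas.
#' @return Relative response in percent (always >= 0).
#' @examples
#' relative_response(1.0, 0.9)  # 10
#' @export
relative_response <- function(i_air, i_gas) {
  if (any(i_air <= 0)) stop("i_air must be positive")
  abs(i_air - i_gas) / i_air * 100
}

#' Virtual sensors from cycle plateaus
#'
#' Collapses each cycle to one value per temperature plateau (the plateau
#' mean), producing one derived "virtual sensor" series per plateau across
#' consecutive cycles — the virtual sensor array of a single
#' temperature-cycled device.
#'
#' @param cycles A `cycle_set` (raw or standardized).
#' @param program A [temperature_program()]; defaults to the set's.
#' @param window_fraction Fraction (0, 1] of each plateau used, taken from
#'   the plateau end; 1 = full plateau, 0.5 = last half (excludes the
#'   thermal transient).
#' @return Object of class `"virtual_sensors"`: matrix cycles x plateaus
#'   with column names `T<temp>`, carrying the cycle metadata.
#' @export
virtual_sensors <- function(cycles, program = cycles$program,
                            window_fraction = 1) {
  stopifnot(inherits(cycles, "cycle_set"))
  if (window_fraction <= 0 || window_fraction > 1) {
    stop("window_fraction must be in (0, 1]")
  }
  spp <- program$samples_per_plateau
  n_keep <- max(1L, as.integer(round(spp * window_fraction)))
  vs <- sapply(seq_len(program$n_plateaus), function(p) {
    idx <- ((p - 1L) * spp + (spp - n_keep + 1L)):((p) * spp)
    rowMeans(cycles$signal[, idx, drop = FALSE])
  })
  vs <- matrix(vs, nrow = nrow(cycles$signal))
  colnames(vs) <- paste0("T", program$plateau_temps)
  structure(vs, class = c("virtual_sensors", "matrix"),
            meta = cycles$meta, plateau_temps = program$plateau_temps)
}

#' Standardized modelling observations from a study
#'
#' Runs the preprocessing chain on every trace of a study — Savitzky-Golay
#' smoothing of the raw trace, cycle segmentation, per-cycle auto-scaling
#' (in that order) — and keeps the modelling observations: exposure-phase
#' cycles after discarding the first `discard` cycles of each exposure
#' (sensor settling). For synthetic-air control traces, the cycles at the
#' same positions as the kept exposure cycles are used so the SA class has
#' comparable observations.
#'
#' @param study A `venose_study` from [make_study()].
#' @param discard Number of leading exposure cycles dropped per exposure.
#' @param smooth Apply Savitzky-Golay smoothing first (default TRUE).
#' @param window_length,polyorder Smoothing parameters, see [sg_smooth()].
#' @return A standardized `cycle_set` whose `meta` carries `gas`,
#'   `conc_ppb` and the source `exposure` index.
#' @export
study_observations <- function(study, discard = 2, smooth = TRUE,
                               window_length = 11, polyorder = 3) {
  stopifnot(inherits(study, "venose_study"))
  cfg <- study$config
  if (discard < 0 || discard >= cfg$exposure_cycles) {
    stop("discard leaves no exposure cycles")
  }
  keep_pos <- cfg$baseline_cycles + seq(discard + 1, cfg$exposure_cycles)
  sig <- NULL
  meta <- NULL
  for (i in seq_along(study$traces)) {
    tr <- study$traces[[i]]
    if (smooth) {
      tr <- sg_smooth(tr, window_length = window_length,
                      polyorder = polyorder)
    }
    cyc <- autoscale_cycles(segment_cycles(tr, cfg$program))
    m <- cyc$meta[keep_pos, , drop = FALSE]
    m$gas <- study$labels$gas[i]
    m$conc_ppb <- study$labels$conc_ppb[i]
    m$exposure <- i
    sig <- rbind(sig, cyc$signal[keep_pos, , drop = FALSE])
    meta <- rbind(meta, m)
  }
  meta$cycle_idx <- seq_len(nrow(meta))
  rownames(meta) <- NULL
  structure(list(signal = sig, meta = meta, program = cfg$program,
                 standardized = TRUE),
            class = "cycle_set")
}
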