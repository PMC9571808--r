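# Phenomenological simulator for a SiCFET gas sensor operated in
# temperature-cycled (dynamic) mode. Replaces hardware + gas-mixing rig so
# every downstream stage can be exercised on data with known ground truth.

#' Temperature-cycled operation program
#'
#' Describes one temperature cycle: an ordered set of temperature plateaus,
#' each held for a fixed duration, sampled at a fixed rate. The default is
#' the five-plateau 360 to 240 degC cycle (descending, 30 degC steps) held
#' 22 s per plateau at 10 Hz, i.e. 1100 samples and 110 s per cycle.
#'
#' @param plateau_temps Ordered plateau temperatures in degC.
#' @param plateau_duration Seconds each plateau is held.
#' @param sampling_rate Acquisition rate in Hz.
#' @return An object of class `"temperature_program"` with derived fields
#'   `samples_per_plateau`, `cycle_samples` and `cycle_seconds`.
#' @examples
#' p <- temperature_program()
#' p$cycle_samples  # 1100
#' @export
temperature_program <- function(plateau_temps = c(360, 330, 300, 270, 240),
                                plateau_duration = 22,
                                sampling_rate = 10) {
  if (length(plateau_temps) < 1L) stop("need at least one plateau")
  if (plateau_duration <= 0) stop("plateau_duration must be positive")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  spp <- plateau_duration * sampling_rate
  if (abs(spp - round(spp)) > 1e-9 || spp < 1) {
    stop("plateau_duration x sampling_rate must be a positive integer")
  }
  spp <- as.integer(round(spp))
  structure(list(
    plateau_temps = as.numeric(plateau_temps),
    plateau_duration = plateau_duration,
    sampling_rate = sampling_rate,
    n_plateaus = length(plateau_temps),
    samples_per_plateau = spp,
    cycle_samples = spp * length(plateau_temps),
    cycle_seconds = plateau_duration * length(plateau_temps)
  ), class = "temperature_program")
}

#' @export
print.temperature_program <- function(x, ...) {
  cat("Temperature program:", paste(x$plateau_temps, collapse = " / "),
      "degC\n")
  cat(sprintf("  %g s per plateau @ %g Hz -> %d samples (%g s) per cycle\n",
              x$plateau_duration, x$sampling_rate,
              x$cycle_samples, x$cycle_seconds))
  invisible(x)
}

#' Gas exposure schedule
#'
#' An ordered sequence of gas segments. Concentration must be 0 for the
#' synthetic-air carrier (`"SA"`) and positive for a VOC segment.
#'
#' @param gas Character vector of gas identifiers among
#'   `"SA"`, `"CH2O"`, `"CH2O2"`, `"CH3COOH"`.
#' @param conc_ppb Segment concentrations in parts per billion.
#' @param duration_s Segment durations in seconds.
#' @return A data frame of class `"exposure_plan"`.
#' @export
exposure_plan <- function(gas, conc_ppb, duration_s) {
  gas <- as.character(gas)
  bad <- setdiff(gas, GASES)
  if (length(bad)) {
    stop("unknown gas_id: ", paste(bad, collapse = ", "))
  }
  if (length(gas) != length(conc_ppb) || length(gas) != length(duration_s)) {
    stop("gas, conc_ppb and duration_s must have equal length")
  }
  if (any(duration_s <= 0)) stop("segment durations must be positive")
  if (any(conc_ppb < 0)) stop("concentrations must be non-negative")
  if (any(gas == "SA" & conc_ppb != 0)) {
    stop("SA segments must have concentration 0")
  }
  if (any(gas != "SA" & conc_ppb <= 0)) {
    stop("VOC segments must have positive concentration")
  }
  structure(data.frame(gas = gas, conc_ppb = as.numeric(conc_ppb),
                       duration_s = as.numeric(duration_s)),
            class = c("exposure_plan", "data.frame"))
}

#' Gas response model for the simulator
#'
#' Steady-state relative response of the sensor at plateau temperature T to
#' gas g at concentration c follows a power-law isotherm
#' R(g, T, c) = A(g, T) * (c / c_ref)^beta (percent), with A given per gas
#' and per plateau. Defaults keep the amplitude ordering
#' CH2O > CH2O2 > CH3COOH at every plateau, with gas-specific temperature
#' profiles (formaldehyde strongest at the hot plateaus, acetic acid
#' flattest and relatively strongest at the cold end) so the standardized
#' cycle shapes differ between gases.
#'
#' @param amplitude Matrix of relative-response amplitudes (percent at
#'   `c_ref`), rows = gases (rownames mandatory), columns = plateaus of the
#'   program the model will be used with.
#' @param beta Isotherm exponent (unitless, sub-linear by default).
#' @param c_ref Reference concentration in ppb.
#' @param tau_gas Gas adsorption/desorption time constant in seconds.
#' @param tau_T Heater/temperature-readout time constant in seconds.
#' @param drift_rate Linear baseline drift as a fraction per hour.
#' @param rw_sd Random-walk drift increment sd per sqrt(second); 0 disables.
#' @param noise_sd Additive Gaussian noise sd as a fraction of the local
#'   baseline current.
#' @param response_sign -1 (default): gas exposure decreases the current;
#'   +1 for an increasing response.
#' @param i_ref Baseline current (arbitrary units) at `t_ref`.
#' @param temp_coef Baseline log-current slope per degC.
#' @param t_ref Reference temperature (degC) for the baseline current.
#' @return An object of class `"gas_response_model"`.
#' @export
gas_response_model <- function(amplitude = NULL,
                               beta = 0.7,
                               c_ref = 1000,
                               tau_gas = 60,
                               tau_T = 2,
                               drift_rate = 0.005,
                               rw_sd = 0,
                               noise_sd = 0.002,
                               response_sign = -1,
                               i_ref = 50,
                               temp_coef = 0.0025,
                               t_ref = 300) {
  if (is.null(amplitude)) {
    amplitude <- rbind(
      CH2O     = c(5.5, 5.0, 4.2, 3.4, 2.8),
      CH2O2    = c(2.6, 3.4, 3.8, 3.0, 2.2),
      CH3COOH  = c(1.0, 1.3, 1.6, 1.9, 2.1)
    )
  }
  amplitude <- as.matrix(amplitude)
  if (is.null(rownames(amplitude))) {
    stop("amplitude must have gas rownames")
  }
  if (any(amplitude < 0)) stop("amplitudes must be non-negative")
  if (beta < 0) stop("beta must be non-negative")
  if (c_ref <= 0) stop("c_ref must be positive")
  if (!response_sign %in% c(-1, 1)) stop("response_sign must be -1 or +1")
  structure(list(amplitude = amplitude, beta = beta, c_ref = c_ref,
                 tau_gas = tau_gas, tau_T = tau_T,
                 drift_rate = drift_rate, rw_sd = rw_sd,
                 noise_sd = noise_sd, response_sign = response_sign,
                 i_ref = i_ref, temp_coef = temp_coef, t_ref = t_ref),
            class = "gas_response_model")
}

#' Steady-state relative response of the model
#'
#' Evaluates R(gas, T, c) = A(gas, T) * (c / c_ref)^beta for every plateau,
#' the generating formula the simulator converges to once transients have
#' settled. Non-negative and monotone non-decreasing in `conc_ppb`.
#'
#' @param model A [gas_response_model()].
#' @param gas A single gas identifier (`"SA"` gives all zeros).
#' @param conc_ppb A single concentration in ppb.
#' @return Numeric vector of per-plateau relative responses in percent.
#' @export
steady_response <- function(model, gas, conc_ppb) {
  stopifnot(inherits(model, "gas_response_model"))
  n_plateau <- ncol(model$amplitude)
  if (identical(gas, "SA") || conc_ppb == 0) return(numeric(n_plateau))
  if (!gas %in% rownames(model$amplitude)) stop("unknown gas_id: ", gas)
  model$amplitude[gas, ] * (conc_ppb / model$c_ref)^model$beta
}

# Smooth, strictly positive baseline current as a function of temperature.
baseline_current <- function(model, temp_c) {
  model$i_ref * exp(model$temp_coef * (temp_c - model$t_ref))
}

# First-order (single-pole) low-pass with time constant tau seconds;
# tau = 0 passes the input through. Initial state = first target value.
first_order <- function(x, tau, dt) {
  if (tau <= 0) return(x)
  a <- 1 - exp(-dt / tau)
  as.numeric(stats::filter(a * x, 1 - a, method = "recursive", init = x[1]))
}

#' Simulate a temperature-cycled sensor trace
#'
#' Generates the drain-current time series of a temperature-cycled sensor
#' following an exposure schedule. Cycles are concatenated continuously
#' from t = 0 regardless of segment boundaries. The measured temperature
#' lags the set program with time constant `tau_T`; gas coverage follows
#' the exposure schedule with time constant `tau_gas`; the current is
#' baseline(T) x (1 + sign x coverage x R(gas, T, c)/100), plus linear /
#' random-walk drift and additive Gaussian noise.
#'
#' @param program A [temperature_program()].
#' @param plan An [exposure_plan()] covering at least one full cycle.
#' @param model A [gas_response_model()].
#' @param seed Integer seed; the trace is deterministic given it.
#' @return A data frame of class `"sensor_trace"` with columns
#'   `time_s, current, T_set_C, T_meas_C, gas, conc_ppb`.
#' @examples
#' pr <- temperature_program()
#' pl <- exposure_plan("SA", 0, 220)
#' tr <- simulate_trace(pr, pl, gas_response_model(), seed = 1)
#' nrow(tr)  # 2200 samples = 2 cycles
#' @export
simulate_trace <- function(program, plan, model, seed) {
  stopifnot(inherits(program, "temperature_program"),
            inherits(plan, "exposure_plan"),
            inherits(model, "gas_response_model"))
  if (missing(seed)) stop("seed must be set explicitly")
  rate <- program$sampling_rate
  dt <- 1 / rate
  total_s <- sum(plan$duration_s)
  n <- as.integer(round(total_s * rate))
  if (n < program$cycle_samples) {
    stop("plan duration must cover at least one full cycle")
  }

  time_s <- (seq_len(n) - 1L) * dt
  # plateau index of each sample under continuous cycling from t = 0
  in_cycle <- (seq_len(n) - 1L) %% program$cycle_samples
  plateau_idx <- in_cycle %/% program$samples_per_plateau + 1L
  t_set <- program$plateau_temps[plateau_idx]
  # warm-up: the sensor cycles continuously before acquisition starts, so
  # filter one unrecorded cycle first to reach periodic steady state
  warm <- program$plateau_temps[rep(seq_len(program$n_plateaus),
                                    each = program$samples_per_plateau)]
  t_meas <- first_order(c(warm, t_set), model$tau_T,
                        dt)[-seq_along(warm)]

  # per-sample segment annotation
  seg_n <- as.integer(round(plan$duration_s * rate))
  seg_id <- rep.int(seq_len(nrow(plan)), seg_n)[seq_len(n)]
  gas <- plan$gas[seg_id]
  conc <- plan$conc_ppb[seg_id]

  # instantaneous steady-state response (percent) at each sample
  r_target <- numeric(n)
  for (s in seq_len(nrow(plan))) {
    if (plan$gas[s] == "SA") next
    rr <- steady_response(model, plan$gas[s], plan$conc_ppb[s])
    sel <- seg_id == s
    r_target[sel] <- rr[plateau_idx[sel]]
  }
  # slow coverage dynamics: 0/1 occupancy filtered with tau_gas; the
  # temperature modulation of the amplitude itself is instantaneous
  coverage <- first_order(as.numeric(gas != "SA"), model$tau_gas, dt)
  response_pct <- coverage * r_target

  base <- baseline_current(model, t_meas)
  current <- base * (1 + model$response_sign * response_pct / 100)

  with_seed(seed, {
    drift <- 1 + model$drift_rate * time_s / 3600
    if (model$rw_sd > 0) {
      drift <- drift + cumsum(rnorm(n, 0, model$rw_sd * sqrt(dt)))
    }
    current <- current * drift
    if (model$noise_sd > 0) {
      current <- current + rnorm(n, 0, model$noise_sd * base)
    }
  })
  if (any(current <= 0)) {
    stop("simulated current reached non-positive values; ",
         "reduce noise/drift or response amplitudes")
  }
  structure(
    data.frame(time_s = time_s, current = current, T_set_C = t_set,
               T_meas_C = t_meas, gas = gas, conc_ppb = conc,
               stringsAsFactors = FALSE),
    class = c("sensor_trace", "data.frame"),
    program = program, model = model, seed = seed
  )
}

#' Generate a full exposure study
#'
#' Emits one trace per exposure following the three-phase protocol
#' (carrier-gas baseline, gas exposure, carrier-gas recovery), with the
#' concentration order randomized within each gas x repetition block to
#' avoid concatenating monotone concentration ramps. Synthetic-air control
#' exposures (all-carrier traces) are appended so "SA" can participate as
#' a class of its own.
#'
#' @param gases VOC identifiers to study.
#' @param concentrations Concentration set in ppb, applied to every gas.
#' @param repetitions Number of repetitions per gas x concentration.
#' @param n_sa Number of synthetic-air control exposures
#'   (default: one per concentration level).
#' @param baseline_cycles,exposure_cycles,recovery_cycles Phase durations
#'   in whole cycles.
#' @param program A [temperature_program()].
#' @param model A [gas_response_model()].
#' @param seed Master seed; every exposure gets a derived child seed.
#' @return An object of class `"venose_study"`: list with `traces` (list of
#'   `sensor_trace`), `labels` (one row per exposure: `exposure, gas,
#'   conc_ppb, seed`) and `config`.
#' @export
make_study <- function(gases = c("CH2O", "CH2O2", "CH3COOH"),
                       concentrations = seq(250, 3000, length.out = 7),
                       repetitions = 1,
                       n_sa = length(concentrations),
                       baseline_cycles = 10,
                       exposure_cycles = 12,
                       recovery_cycles = 4,
                       program = temperature_program(),
                       model = gas_response_model(),
                       seed = 1) {
  if (length(gases) == 0) stop("gas list must not be empty")
  bad <- setdiff(gases, setdiff(GASES, "SA"))
  if (length(bad)) stop("unknown gas_id: ", paste(bad, collapse = ", "))
  if (repetitions < 1) stop("repetitions must be >= 1")
  if (length(concentrations) == 0 || any(concentrations <= 0)) {
    stop("concentrations must be positive")
  }
  cyc_s <- program$cycle_seconds

  # randomized concentration order per gas x repetition block
  label <- do.call(rbind, lapply(seq_len(repetitions), function(r) {
    do.call(rbind, lapply(gases, function(g) {
      data.frame(gas = g, conc_ppb = concentrations, rep = r)
    }))
  }))
  if (n_sa > 0) {
    label <- rbind(label,
                   data.frame(gas = "SA", conc_ppb = 0, rep = seq_len(n_sa)))
  }
  ord_seed <- child_seeds(seed, 1L)
  with_seed(ord_seed, {
    blocks <- split(seq_len(nrow(label)),
                    interaction(label$gas, label$rep, drop = TRUE))
    for (b in blocks) {
      label$conc_ppb[b] <- label$conc_ppb[b[sample.int(length(b))]]
    }
  })
  n_exp <- nrow(label)
  seeds <- child_seeds(seed + 1, n_exp)

  traces <- vector("list", n_exp)
  for (i in seq_len(n_exp)) {
    g <- label$gas[i]
    if (g == "SA") {
      plan <- exposure_plan("SA", 0,
        (baseline_cycles + exposure_cycles + recovery_cycles) * cyc_s)
    } else {
      plan <- exposure_plan(
        gas = c("SA", g, "SA"),
        conc_ppb = c(0, label$conc_ppb[i], 0),
        duration_s = c(baseline_cycles, exposure_cycles, recovery_cycles) *
          cyc_s)
    }
    traces[[i]] <- simulate_trace(program, plan, model, seed = seeds[i])
  }
  structure(list(
    traces = traces,
    labels = data.frame(exposure = seq_len(n_exp), gas = label$gas,
                        conc_ppb = label$conc_ppb, seed = seeds),
    config = list(gases = gases, concentrations = concentrations,
                  repetitions = repetitions, n_sa = n_sa,
                  baseline_cycles = baseline_cycles,
                  exposure_cycles = exposure_cycles,
                  recovery_cycles = recovery_cycles,
                  program = program, model = model, seed = seed)
  ), class = "venose_study")
}

#' @export
print.venose_study <- function(x, ...) {
  cat("Virtual e-nose study:", length(x$traces), "exposures\n")
  print(table(x$labels$gas))
  invisible(x)
}

#' Write / read a sensor trace as CSV
#'
#' Plain-text interchange format: one row per sample with columns
#' `time_s,current,T_set_C,T_meas_C,gas,conc_ppb`.
#'
#' @param trace A `sensor_trace` data frame.
#' @param path File path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `sensor_trace` data frame.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "current", "T_set_C", "T_meas_C", "gas", "conc_ppb")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns: ", paste(need, collapse = ","))
  }
  structure(df[need], class = c("sensor_trace", "data.frame"))
}
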