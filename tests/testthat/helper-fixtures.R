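# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# noise- and drift-free model: the generating formula is exactly
# recoverable from simulated traces
quiet_model <- function(...) {
  gas_response_model(noise_sd = 0, drift_rate = 0, ...)
}

default_program <- function() memo("program", temperature_program())

# one noiseless exposure trace (10 baseline / 12 exposure / 4 recovery
# cycles) for a given gas and concentration
quiet_exposure <- function(gas = "CH2O", conc = 1000, seed = 42) {
  key <- paste("exposure", gas, conc, seed, sep = "_")
  memo(key, {
    pr <- default_program()
    plan <- exposure_plan(c("SA", gas, "SA"), c(0, conc, 0),
                          c(10, 12, 4) * pr$cycle_seconds)
    simulate_trace(pr, plan, quiet_model(), seed = seed)
  })
}

tiny_study <- function() memo("tiny_study", make_fixtures("tiny", seed = 7))

tiny_features <- function() {
  memo("tiny_features",
       extract_features(study_observations(tiny_study(), discard = 1)))
}

demo_features <- function() {
  memo("demo_features", {
    study <- make_fixtures("demo", seed = 1)
    extract_features(study_observations(study, discard = 2))
  })
}

# small multi-class Gaussian problem with well-separated classes
separable_classes <- function(n_per = 12, p = 5, shift = 8, seed = 3) {
  set.seed(seed)
  x <- do.call(rbind, lapply(0:3, function(k) {
    matrix(rnorm(n_per * p, mean = k * shift), n_per, p)
  }))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = factor(rep(letters[1:4], each = n_per)))
}
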