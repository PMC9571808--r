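# Simulator: cycle geometry, determinism, response model, study design.

test_that("trace geometry follows the temperature program", {
  pr <- default_program()
  expect_equal(pr$cycle_samples, 1100)
  expect_equal(pr$cycle_seconds, 110)
  tr <- simulate_trace(pr, exposure_plan("SA", 0, 220), quiet_model(),
                       seed = 1)
  expect_equal(nrow(tr), 2200)
  expect_equal(diff(tr$time_s), rep(0.1, 2199))
  expect_true(all(tr$current > 0))
  expect_equal(nrow(segment_cycles(tr, pr)$signal), 2)
})

test_that("zero noise and drift make consecutive cycles identical", {
  pr <- default_program()
  tr <- simulate_trace(pr, exposure_plan("SA", 0, 220), quiet_model(),
                       seed = 5)
  expect_identical(tr$current[1:1100], tr$current[1101:2200])
  expect_identical(tr$T_meas_C[1:1100], tr$T_meas_C[1101:2200])
})

test_that("simulation is deterministic given the seed", {
  pr <- default_program()
  plan <- exposure_plan(c("SA", "CH2O", "SA"), c(0, 800, 0),
                        c(110, 220, 110))
  m <- gas_response_model()  # noisy
  expect_identical(simulate_trace(pr, plan, m, seed = 11),
                   simulate_trace(pr, plan, m, seed = 11))
  tr_a <- simulate_trace(pr, plan, m, seed = 11)
  tr_b <- simulate_trace(pr, plan, m, seed = 12)
  expect_false(identical(tr_a$current, tr_b$current))
  # noise realization does not move segment boundaries
  expect_identical(tr_a$gas, tr_b$gas)
  expect_identical(tr_a$conc_ppb, tr_b$conc_ppb)
})

test_that("steady response follows the power-law isotherm", {
  m <- quiet_model()
  # monotone non-decreasing in concentration, at every plateau
  concs <- c(250, 500, 1000, 2000, 3000)
  for (g in c("CH2O", "CH2O2", "CH3COOH")) {
    rr <- sapply(concs, function(cc) steady_response(m, g, cc))
    expect_true(all(rr >= 0))
    expect_true(all(apply(rr, 1, diff) > 0))
  }
  # closed form at the reference concentration
  expect_equal(steady_response(m, "CH2O", m$c_ref),
               unname(m$amplitude["CH2O", ]))
  expect_equal(steady_response(m, "SA", 0), rep(0, 5))
})

test_that("default amplitudes keep the gas ordering at every plateau", {
  m <- gas_response_model()
  for (cc in c(250, 1000, 3000)) {
    r_ch2o <- steady_response(m, "CH2O", cc)
    r_ch2o2 <- steady_response(m, "CH2O2", cc)
    r_acoh <- steady_response(m, "CH3COOH", cc)
    expect_true(all(r_ch2o > r_ch2o2))
    expect_true(all(r_ch2o2 > r_acoh))
  }
})

test_that("higher concentration gives larger per-plateau response", {
  pr <- default_program()
  vs_at <- function(conc) {
    cyc <- segment_cycles(quiet_exposure("CH2O", conc), pr)
    virtual_sensors(cyc, pr)
  }
  vs_hi <- vs_at(1000); vs_lo <- vs_at(250)
  rr_hi <- relative_response(vs_hi[10, ], vs_hi[22, ])
  rr_lo <- relative_response(vs_lo[10, ], vs_lo[22, ])
  expect_true(all(rr_hi > rr_lo))
  # and both match the generating formula
  m <- quiet_model()
  expect_equal(rr_hi, steady_response(m, "CH2O", 1000),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(rr_lo, steady_response(m, "CH2O", 250),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("simulator input validation", {
  pr <- default_program()
  m <- quiet_model()
  expect_error(exposure_plan("N2", 100, 100), "unknown gas_id")
  expect_error(exposure_plan("CH2O", 500, -5), "positive")
  expect_error(exposure_plan("SA", 100, 100), "concentration 0")
  expect_error(simulate_trace(pr, exposure_plan("SA", 0, 50), m, seed = 1),
               "at least one full cycle")
  expect_error(simulate_trace(pr, exposure_plan("SA", 0, 220), m),
               "seed")
  expect_error(temperature_program(sampling_rate = 0), "positive")
  expect_error(make_study(gases = character(0)), "empty")
})

test_that("make_study emits one labelled trace per exposure", {
  study <- make_study(gases = c("CH2O", "CH2O2", "CH3COOH"),
                      concentrations = c(500, 1500, 3000),
                      repetitions = 1, n_sa = 0,
                      baseline_cycles = 1, exposure_cycles = 2,
                      recovery_cycles = 1, seed = 21)
  expect_equal(nrow(study$labels), 9)  # 3 gases x 3 concentrations
  expect_equal(length(study$traces), 9)
  expect_equal(sort(unique(study$labels$gas)),
               c("CH2O", "CH2O2", "CH3COOH"))
  # every gas sees the full concentration set
  tab <- table(study$labels$gas, study$labels$conc_ppb)
  expect_true(all(tab == 1))
  # reproducible
  study2 <- make_study(gases = c("CH2O", "CH2O2", "CH3COOH"),
                       concentrations = c(500, 1500, 3000),
                       repetitions = 1, n_sa = 0,
                       baseline_cycles = 1, exposure_cycles = 2,
                       recovery_cycles = 1, seed = 21)
  expect_identical(study$labels, study2$labels)
  expect_identical(study$traces[[5]], study2$traces[[5]])
})

test_that("concentration order is randomized, not sorted", {
  differs <- vapply(1:20, function(s) {
    st <- make_study(gases = "CH2O",
                     concentrations = seq(250, 3000, length.out = 7),
                     repetitions = 1, n_sa = 0,
                     baseline_cycles = 1, exposure_cycles = 1,
                     recovery_cycles = 1, seed = s)
    is.unsorted(st$labels$conc_ppb)
  }, logical(1))
  expect_true(any(differs))
})

test_that("trace CSV round-trips", {
  tr <- simulate_trace(default_program(), exposure_plan("SA", 0, 110),
                       quiet_model(), seed = 2)
  path <- tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_equal(back$current, tr$current, tolerance = 1e-12)
  expect_identical(back$gas, tr$gas)
  unlink(path)
})
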