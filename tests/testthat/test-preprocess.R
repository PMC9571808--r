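# Preprocessing: segmentation, smoothing, auto-scaling, relative
# response, virtual sensors.

test_that("segmentation floors to whole cycles and drops the tail", {
  pr <- default_program()
  tr <- simulate_trace(pr, exposure_plan("SA", 0, 235), quiet_model(),
                       seed = 1)
  expect_equal(nrow(tr), 2350)
  cyc <- segment_cycles(tr, pr)
  expect_equal(nrow(cyc$signal), 2)  # 150 samples discarded
  expect_error(
    segment_cycles(tr[1:1000, ], pr), "shorter than one cycle")
})

test_that("cycle phase tagging follows the majority rule", {
  pr <- default_program()
  m <- quiet_model()
  # gas on after 55 s: cycle 1 is 550 SA + 550 gas samples, the 50% tie
  # resolves towards the later phase (exposure)
  tr <- simulate_trace(pr, exposure_plan(c("SA", "CH2O"), c(0, 900),
                                         c(55, 165)), m, seed = 1)
  cyc <- segment_cycles(tr, pr)
  expect_equal(cyc$meta$phase, c("exposure", "exposure"))
  expect_equal(cyc$meta$gas[1], "CH2O")
  # gas on after 60 s: 600 SA samples dominate cycle 1
  tr2 <- simulate_trace(pr, exposure_plan(c("SA", "CH2O"), c(0, 900),
                                          c(60, 160)), m, seed = 1)
  cyc2 <- segment_cycles(tr2, pr)
  expect_equal(cyc2$meta$phase, c("baseline", "exposure"))
  expect_equal(cyc2$meta$gas[1], "SA")
  # full protocol tags the three phases in order
  cyc3 <- segment_cycles(quiet_exposure(), pr)
  expect_equal(cyc3$meta$phase,
               rep(c("baseline", "exposure", "recovery"), c(10, 12, 4)))
})

test_that("segmenting a concatenation of whole cycles is the identity", {
  pr <- default_program()
  tr <- quiet_exposure()
  cyc <- segment_cycles(tr, pr)
  rebuilt <- tr
  rebuilt$current <- as.vector(t(cyc$signal))
  expect_equal(segment_cycles(rebuilt, pr)$signal, cyc$signal)
})

test_that("Savitzky-Golay smoothing preserves low-order polynomials", {
  t <- seq(0, 10, by = 0.1)
  quad <- 2 + 0.5 * t - 0.3 * t^2
  expect_equal(sg_smooth(quad, 11, 3), quad, tolerance = 1e-9)
  expect_equal(sg_smooth(rep(4, 200), 11, 3), rep(4, 200),
               tolerance = 1e-12)
  set.seed(1)
  noise <- rnorm(500)
  expect_lt(var(sg_smooth(noise, 11, 3)), var(noise))
  expect_error(sg_smooth(noise, 10, 3), "odd")
  expect_error(sg_smooth(noise, 11, 11), "polyorder")
  expect_error(sg_smooth(rnorm(5), 11, 3), "window longer than signal")
})

test_that("auto-scaling standardizes to mean 0 and sample sd 100", {
  expect_equal(autoscale_cycle(c(1, 2, 3)), c(-100, 0, 100))
  set.seed(2)
  y <- rnorm(1100, mean = 40, sd = 3)
  z <- autoscale_cycle(y)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 100, tolerance = 1e-9 * 100)
  # affine invariance (positive gain) and exact additive-drift removal
  expect_equal(autoscale_cycle(2.5 * y + 7), z, tolerance = 1e-9)
  expect_equal(autoscale_cycle(y + 123.4), z, tolerance = 1e-9)
  expect_error(autoscale_cycle(rep(5, 100)), "constant cycle")
})

test_that("auto-scaling a cycle set standardizes every row", {
  cyc <- segment_cycles(quiet_exposure(), default_program())
  std <- autoscale_cycles(cyc)
  expect_true(std$standardized)
  expect_equal(rowMeans(std$signal), rep(0, nrow(std$signal)),
               tolerance = 1e-9)
  expect_equal(apply(std$signal, 1, sd), rep(100, nrow(std$signal)),
               tolerance = 1e-9)
  expect_equal(std$signal[1, ], autoscale_cycle(cyc$signal[1, ]))
})

test_that("relative response reproduces the worked values", {
  expect_equal(relative_response(1.0, 0.9), 10.0)
  expect_equal(relative_response(2.0, 2.5), 25.0)
  for (x in c(0.1, 1, 57)) expect_equal(relative_response(x, x), 0)
  expect_true(all(relative_response(runif(50, 1, 2),
                                    runif(50, 0.5, 3)) >= 0))
  expect_error(relative_response(0, 1), "positive")
  expect_error(relative_response(-2, 1), "positive")
})

test_that("virtual sensors collapse cycles to one series per plateau", {
  pr <- default_program()
  cyc <- segment_cycles(quiet_exposure(), pr)
  vs <- virtual_sensors(cyc, pr)
  expect_equal(ncol(vs), 5)
  expect_equal(colnames(vs), paste0("T", c(360, 330, 300, 270, 240)))
  expect_equal(nrow(vs), nrow(cyc$signal))
  # constant cycles give constant virtual sensors
  const <- cyc
  const$signal <- matrix(3.7, 2, pr$cycle_samples)
  const$meta <- cyc$meta[1:2, ]
  expect_true(all(virtual_sensors(const, pr) == 3.7))
  expect_error(virtual_sensors(cyc, pr, window_fraction = 0), "in \\(0, 1]")
})

test_that("zero-noise plateau responses recover the generating formula", {
  pr <- default_program()
  m <- quiet_model()
  for (g in c("CH2O", "CH3COOH")) {
    cyc <- segment_cycles(quiet_exposure(g, 1800), pr)
    vs <- virtual_sensors(cyc, pr)
    rr <- relative_response(vs[10, ], vs[22, ])
    truth <- steady_response(m, g, 1800)
    expect_equal(rr, truth, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("observations are smoothed before standardizing", {
  study <- tiny_study()
  obs <- study_observations(study, discard = 1)
  cfg <- study$config
  keep <- cfg$baseline_cycles + 2:cfg$exposure_cycles
  tr <- study$traces[[1]]
  # same order as the pipeline: smooth the trace, then standardize cycles
  manual <- autoscale_cycles(segment_cycles(sg_smooth(tr), cfg$program))
  expect_equal(obs$signal[seq_along(keep), ],
               manual$signal[keep, ])
  # the reversed order gives a different result
  reversed <- sg_smooth(autoscale_cycles(segment_cycles(tr, cfg$program)))
  expect_false(isTRUE(all.equal(manual$signal[keep, ],
                                reversed$signal[keep, ])))
})

test_that("study observations carry labels and drop settling cycles", {
  study <- tiny_study()
  obs <- study_observations(study, discard = 1)
  cfg <- study$config
  per_exposure <- cfg$exposure_cycles - 1
  expect_equal(nrow(obs$signal),
               per_exposure * length(study$traces))
  expect_equal(unname(table(obs$meta$gas)["SA"]),
               as.integer(per_exposure * cfg$n_sa))
  expect_error(study_observations(study, discard = 99), "no exposure")
})
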