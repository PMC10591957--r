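test_that("gradient interpolation matches the piecewise-linear profile", {
  g <- gradient_profile()
  expect_equal(gradient_percent_b(g, 3), 8)
  expect_equal(gradient_percent_b(g, 33), 32)
  expect_equal(gradient_percent_b(g, 18), 20)    # midpoint of the 8-32 ramp
  expect_equal(gradient_percent_b(g, 0), 4)
  expect_error(gradient_percent_b(g, 60), "outside")
  expect_error(gradient_percent_b(g, -1), "outside")
})

test_that("elution times invert the gradient ramp", {
  g <- gradient_profile()
  # %B = 20 is reached at min 18 on the 8-32 ramp
  expect_equal(diaqc:::gradient_crossing_min(g, 20), 18)
  expect_equal(diaqc:::gradient_crossing_min(g, 8), 3)
})

test_that("the simulator is deterministic under a fixed seed", {
  cfg <- sim_config(n_precursors = 30L, seed = 5L, run_duration_min = 5)
  cyc <- duty_cycle(equal_mz_windows(c(380, 1400), 4), max_injection_ms = 251)
  a <- simulate_run(cfg, cyc)
  b <- simulate_run(cfg, cyc)
  expect_identical(a$scans$scans, b$scans$scans)
  expect_identical(a$report_unfiltered, b$report_unfiltered)
  expect_identical(a$truth$identified_direct, b$truth$identified_direct)
})

test_that("an empty precursor set still schedules scans with baseline TIC", {
  cfg <- sim_config(n_precursors = 0L, seed = 2L, run_duration_min = 2)
  cyc <- duty_cycle(equal_mz_windows(c(380, 1400), 2), max_injection_ms = 251)
  sim <- simulate_run(cfg, cyc)
  expect_equal(nrow(sim$report), 0L)
  expect_gt(n_scans(sim$scans), 0L)
  expect_true(all(sim$scans$scans$tic == cfg$noise_floor))
  expect_true(all(sim$scans$scans$injection_time_ms == cfg$max_injection_ms))
})

test_that("injection times follow the AGC accumulation law exactly", {
  sim <- small_sim()
  cfg <- small_sim_cfg()
  s <- sim$scans$scans
  expect_equal(s$injection_time_ms,
               pmin(cfg$max_injection_ms, cfg$agc_target / s$tic))
  # zero-analyte windows sit at the ceiling
  empty_ms2 <- s$ms_level == 2L & s$tic <= cfg$noise_floor
  expect_gt(sum(empty_ms2), 0)
  expect_true(all(s$injection_time_ms[empty_ms2] == cfg$max_injection_ms))
})

test_that("channel mass offsets are one mTRAQ label per charge", {
  sim <- small_sim()
  tr <- sim$truth
  d0 <- tr[tr$channel == "d0", ]
  d4 <- tr[tr$channel == "d4", ]
  d8 <- tr[tr$channel == "d8", ]
  expect_equal(d4$mz - d0$mz, 4.0071 / d0$charge)
  expect_equal(d8$mz - d0$mz, 2 * 4.0071 / d0$charge)
})

test_that("simulated m/z values skew toward the lower half of the range", {
  cfg <- sim_config(n_precursors = 2000L, seed = 77L, run_duration_min = 0.5)
  cyc <- duty_cycle(equal_mz_windows(c(380, 1400), 2))
  sim <- simulate_run(cfg, cyc)
  d0 <- sim$truth[sim$truth$channel == "d0", ]
  frac_low <- mean(d0$mz < mean(cfg$mz_range))
  expect_gt(frac_low, 0.5)
  expect_lt(frac_low, 0.75)
})

test_that("translated identifications require a directly identified sibling", {
  sim <- small_sim()
  tr <- sim$truth
  if (any(tr$translated)) {
    direct_by_prec <- tapply(tr$identified_direct, tr$precursor, any)
    expect_true(all(direct_by_prec[as.character(tr$precursor[tr$translated])]))
    expect_true(all(!tr$identified_direct[tr$translated]))
  }
  expect_gt(sum(tr$translated), 0)
})

test_that("the emitted report is valid DIA-NN dialect and matches truth", {
  sim <- small_sim()
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(sim$report_unfiltered, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tab <- read_report(f, q_threshold = 0.01)
  expect_equal(nrow(tab), nrow(sim$report))
  expect_equal(sum(tab$translated), sum(sim$truth$translated))
  # RT minutes in the report convert back to apex seconds
  expect_equal(sort(unique(tab$rt_seconds)),
               sort(unique(sim$truth$apex_s[sim$truth$identified_direct |
                                              sim$truth$translated])),
               tolerance = 1e-9)
})

test_that("simulated bundles land on disk and reload", {
  sim <- small_sim()
  d <- withr::local_tempdir()
  write_sim_bundle(sim, d)
  expect_true(file.exists(file.path(d, "scans.mzML")))
  expect_true(file.exists(file.path(d, "report.tsv")))
  expect_true(file.exists(file.path(d, "truth.tsv")))
  back <- read_mzml_scans(file.path(d, "scans.mzML"))
  expect_equal(n_scans(back), n_scans(sim$scans))
})

test_that("config validation names offending fields", {
  expect_error(sim_config(n_precursors = 10), "seed")
  expect_error(sim_config(seed = 1, channels = data.frame(
    label = "d0", factor = 1, presence = 2)), "presence")
})
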