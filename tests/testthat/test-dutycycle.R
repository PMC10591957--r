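cyc <- function(n_ms2, n_ms1 = 1L, max_it = 300, rp = 70000L, ...) {
  duty_cycle(equal_mz_windows(c(380, 1400), n_ms2), n_ms1 = n_ms1,
             resolving_power = rp, max_injection_ms = max_it, ...)
}

test_that("transient durations follow the resolving-power doubling law", {
  expect_equal(transient_ms(70000), 256)
  expect_equal(transient_ms(140000), 512)
  expect_equal(transient_ms(35000), 128)
  expect_equal(transient_ms(17500), 64)
  expect_error(transient_ms(60000), "unsupported")
  # the table is a configurable default
  expect_equal(transient_ms(15000, table = c("15000" = 32)), 32)
})

test_that("scan time is the max of transient and injection plus overhead", {
  expect_equal(scan_time_ms(cyc(2, max_it = 300)), 300)
  expect_equal(scan_time_ms(cyc(2, max_it = 251)), 256)
  expect_equal(scan_time_ms(cyc(2, max_it = 256, overhead_ms = 10)), 266)
})

test_that("cycle duration reproduces the fast and slow method timings", {
  expect_equal(cycle_time_s(cyc(2)), 0.9)
  expect_equal(cycle_time_s(cyc(16)), 5.1)
  expect_equal(cycle_time_s(cyc(1, n_ms1 = 0L, ms1_positions = integer(0))),
               0.3)
})

test_that("cycle duration is linear in the window count", {
  base <- cycle_time_s(cyc(4))
  for (n in 5:10) {
    expect_equal(cycle_time_s(cyc(n)), base + (n - 4) * 0.3)
  }
})

test_that("MS1 sampling interval is the max wrap-around gap", {
  expect_equal(ms1_sampling_interval_s(cyc(2)), 0.9)
  # two evenly placed survey scans nearly halve the sampling interval
  even <- cyc(8, n_ms1 = 2L, max_it = 251)
  expect_equal(ms1_sampling_interval_s(even), 5 * 0.256)
  expect_equal(cycle_time_s(even) / ms1_sampling_interval_s(even), 2,
               tolerance = 0.15)
  # adjacent survey scans leave a 9-scan gap
  adj <- cyc(8, n_ms1 = 2L, ms1_positions = c(0L, 1L), max_it = 251)
  expect_equal(ms1_sampling_interval_s(adj), 9 * 0.256)
})

test_that("MS1 gap agrees with a brute-force pass over the scan schedule", {
  for (pos in list(c(0L, 5L), c(0L, 1L), c(2L, 7L), c(0L, 3L, 6L))) {
    spec <- cyc(10L - length(pos), n_ms1 = length(pos), ms1_positions = pos,
                max_it = 251)
    # unroll three cycles and measure gaps between MS1 slots directly
    sched <- cycle_schedule(spec)
    slots <- which(rep(sched$ms_level, 3) == 1L)
    gap <- max(diff(slots)) * scan_time_ms(spec) / 1000
    expect_equal(ms1_sampling_interval_s(spec), gap)
  }
})

test_that("apex sampling ratio follows the Gaussian closed form", {
  pk <- elution_peak(sigma_s = 2)
  expect_equal(apex_sampling_ratio(pk, 4, phase = 0), 1.0)
  expect_equal(apex_sampling_ratio(pk, 4, phase = 2), exp(-0.5))
  expect_equal(apex_sampling_ratio(pk, 4, phase = "median"), exp(-1 / 8))
})

test_that("median apex loss matches Monte-Carlo phase sampling", {
  set.seed(31)
  pk <- elution_peak(sigma_s = 2)
  delta <- 4
  phases <- runif(2e4, 0, delta)
  mc <- median(vapply(phases, function(p) apex_sampling_ratio(pk, delta, p),
                      numeric(1)))
  expect_equal(mc, exp(-delta^2 / (32 * pk$sigma_s^2)), tolerance = 0.01)
})

test_that("apex sampling degrades monotonically with the interval", {
  pk <- elution_peak(sigma_s = 2)
  r <- vapply(seq(0.1, 6, by = 0.1), function(d) apex_sampling_ratio(pk, d),
              numeric(1))
  expect_true(all(diff(r) < 0))
  expect_equal(apex_sampling_ratio(pk, 1e-9), 1, tolerance = 1e-6)
})

test_that("slow cycles lose more apex signal than fast ones at any width", {
  for (sigma in c(0.5, 1, 2, 3)) {
    pk <- elution_peak(sigma_s = sigma)
    expect_lt(log2(apex_sampling_ratio(pk, 5.1)),
              log2(apex_sampling_ratio(pk, 0.9)))
  }
})

test_that("points per peak scale with base width over cycle time", {
  pk <- elution_peak(sigma_s = 2)
  expect_equal(points_per_peak(pk, 0.9), 8 / 0.9)
  expect_equal(points_per_peak(pk, 5.1), 8 / 5.1)
  expect_gt(points_per_peak(pk, 0.01), points_per_peak(pk, 0.1))
})

test_that("the cycle schedule lays out slots in order with MS1 placement", {
  spec <- cyc(8, n_ms1 = 2L, max_it = 251)
  sched <- cycle_schedule(spec)
  expect_equal(nrow(sched), 10L)
  expect_equal(which(sched$ms_level == 1L) - 1L, spec$ms1_positions)
  expect_equal(sched$end_ms - sched$start_ms, rep(scan_time_ms(spec), 10))
  expect_equal(sched$window_index[sched$ms_level == 2L], 1:8)
})
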