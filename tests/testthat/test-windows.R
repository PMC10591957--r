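test_that("equal-width windows tile the range exactly", {
  s <- equal_mz_windows(c(380, 1400), 8)
  expect_equal(s$width, rep(127.5, 8))
  expect_length(validate_scheme(s), 0)

  s1 <- equal_mz_windows(c(380, 1400), 1)
  expect_equal(c(s1$lower_mz, s1$upper_mz), c(380, 1400))

  s4 <- equal_mz_windows(c(0, 100), 4)
  expect_equal(s4$width, rep(25, 4))
  expect_error(equal_mz_windows(c(380, 1400), 0), "positive")
})

test_that("equal-TIC windows interpolate boundaries within bins", {
  # uniform ion current reduces to equal widths
  h <- list(bin_edges = seq(380, 1400, by = 20),
            bin_mass = rep(1, 51))
  s <- equal_tic_windows(h, c(380, 1400), 8)
  expect_equal(s$width, rep(127.5, 8), tolerance = 1e-9)

  # hand-computed cumulative interpolation: masses (3, 1), cut at 2/3 of bin 1
  h2 <- list(bin_edges = c(380, 400, 420), bin_mass = c(3, 1))
  s2 <- equal_tic_windows(h2, c(380, 420), 2)
  expect_equal(s2$upper_mz[1], 380 + (2 / 3) * 20, tolerance = 1e-9)

  expect_equal(nrow(equal_tic_windows(h2, c(380, 420), 1)), 1L)
  h0 <- list(bin_edges = c(380, 420), bin_mass = 0)
  expect_error(equal_tic_windows(h0, c(380, 420), 2), "degenerate")
})

test_that("equal-precursor windows cut at midpoints of order statistics", {
  s <- equal_precursor_windows(c(400, 500, 600, 700), c(380, 1400), 2)
  expect_equal(s$upper_mz[1], 550)
  counts <- table(assign_window(s, c(400, 500, 600, 700)))
  expect_equal(as.numeric(counts), c(2, 2))

  mzs <- seq(400, 1100, by = 100)
  s2 <- equal_precursor_windows(mzs, c(380, 1400), 4)
  expect_equal(as.numeric(table(assign_window(s2, mzs))), rep(2, 4))

  expect_error(equal_precursor_windows(c(400, 500), c(380, 1400), 3), "fewer")
})

test_that("equal-precursor counts differ by at most one (brute-force recount)", {
  for (seed in 1:5) {
    set.seed(seed)
    mzs <- draw <- exp(runif(1000, log(390), log(1390)))
    s <- equal_precursor_windows(mzs, c(380, 1400), 8)
    expect_length(validate_scheme(s), 0)
    counts <- tabulate(assign_window(s, mzs), nbins = 8)
    expect_lte(max(counts) - min(counts), 1)
    expect_lte(max(abs(counts - 125)), 1)
  }
})

test_that("ties shift boundaries while keeping counts within one", {
  # the naive median cut would land inside the tied pair at 700
  mzs <- c(400, 500, 600, 700, 700, 800, 900)
  s <- equal_precursor_windows(mzs, c(380, 1400), 2)
  expect_length(validate_scheme(s), 0)
  expect_equal(s$upper_mz[1], 650)
  counts <- tabulate(assign_window(s, mzs), nbins = 2)
  expect_lte(max(counts) - min(counts), 1)
})

test_that("stacked widths reach the instrument range upper edge", {
  expect_equal(scheme_upper_edge(c(240, 780), 380), 1400)
  expect_equal(scheme_upper_edge(rep(127.5, 8), 380), 1400)
  expect_equal(scheme_upper_edge(c(100, 64, 61, 66, 91, 100, 153, 385), 380), 1400)
})

test_that("published-style method tables validate as contiguous tilings", {
  width_sets <- list(
    c(240, 780),
    c(120, 120, 200, 580),
    c(80, 80, 80, 120, 240, 420),
    c(60, 60, 60, 60, 100, 100, 290, 290),
    c(50, 50, 50, 50, 50, 75, 75, 150, 150, 320),
    c(40, 40, 40, 40, 40, 40, 60, 60, 120, 120, 210, 210),
    c(30, 30, 30, 30, 30, 30, 30, 30, 50, 50, 50, 50, 145, 145, 145, 145),
    rep(127.5, 8),
    c(100, 64, 61, 66, 91, 100, 153, 385),
    c(84, 63, 49, 66, 59, 101, 176, 422))
  for (w in width_sets) {
    s <- scheme_from_widths(w, 380)
    expect_length(validate_scheme(s), 0)
    expect_equal(s$upper_mz[nrow(s)], 1400)
  }
})

test_that("validate_scheme reports violations instead of raising", {
  s <- window_scheme(c(380, 500), c(500, 1400))
  attr(s, "range") <- c(380, 1500)
  v <- validate_scheme(s)
  expect_gt(length(v), 0)
  expect_match(paste(v, collapse = "; "), "upper edge")

  gap <- window_scheme(c(380, 600), c(500, 1400), range = c(380, 1400))
  expect_match(paste(validate_scheme(gap), collapse = "; "), "contiguous")
})

test_that("boundary assignment is half-open: boundary values go up", {
  s <- equal_mz_windows(c(380, 1400), 8)
  expect_equal(assign_window(s, 507.5), 2L)   # exactly on the first boundary
  expect_equal(assign_window(s, 380), 1L)
  expect_true(is.na(assign_window(s, 1400)))  # upper range edge is exclusive
})

test_that("rounding boundaries to the export grid keeps a valid tiling", {
  set.seed(5)
  s <- equal_precursor_windows(runif(200, 390, 1390), c(380, 1400), 8)
  r <- round_scheme(s, grid_th = 0.5)
  expect_length(validate_scheme(r), 0)
  inner <- r$lower_mz[-1]
  expect_equal(inner, round(inner * 2) / 2)
})

test_that("all three strategies validate on a simulated run", {
  sim <- small_sim()
  rng <- c(380, 1400)
  h <- mz_histogram(sim$scans, range = rng)
  tab <- sim$report
  for (s in list(equal_mz_windows(rng, 8),
                 equal_tic_windows(h, rng, 8),
                 equal_precursor_windows(tab$precursor_mz, rng, 8))) {
    expect_length(validate_scheme(s), 0)
  }
})

test_that("scheme TSV and method-table text are written", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scheme(equal_mz_windows(c(380, 1400), 8), f)
  d <- read.delim(f)
  expect_equal(d$width, rep(127.5, 8))
  txt <- readLines(paste0(f, ".txt"))
  expect_match(txt, "starting at 380 mz")
  expect_match(txt, "127.5Th")
})
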