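test_that("Jaccard completeness handles the standard set cases", {
  expect_equal(jaccard_completeness(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_completeness(c("a"), c("b")), 0)
  expect_equal(jaccard_completeness(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_warning(j <- jaccard_completeness(character(0), character(0)), "empty")
  expect_equal(j, 1)
})

test_that("completeness matrix is symmetric with unit diagonal", {
  tab <- toy_table(seq = c("AK", "BK", "AK", "BK", "CK", "AK"),
                   channel = c("d0", "d0", "d4", "d4", "d4", "d8"))
  M <- completeness_matrix(tab, by = "channel")
  expect_equal(M, t(M))
  expect_equal(diag(M), c(d0 = 1, d4 = 1, d8 = 1))
  # {AK,BK} within {AK,BK,CK}: J = 2/3
  expect_equal(M["d0", "d4"], 2 / 3)
  # single group errors
  expect_error(completeness_matrix(toy_table(seq = "AK"), by = "channel"),
               "two groups")
})

test_that("protein CV follows the sample-SD definition", {
  # hand-walked oracle: cell-median normalization, peptide relative levels,
  # then sample-SD CV per protein
  tab <- toy_table(seq = c("AK", "BK", "AK", "BK"),
                   run = c("r1", "r1", "r2", "r2"),
                   ms1 = c(20, 40, 10, 10))
  v_r1 <- c(20, 40) / median(c(20, 40))   # (2/3, 4/3)
  v_r2 <- c(10, 10) / median(c(10, 10))   # (1, 1)
  rel_r1 <- v_r1 / c(mean(c(v_r1[1], v_r2[1])), mean(c(v_r1[2], v_r2[2])))
  qv <- quant_variability(tab, min_peptides = 2)
  expect_equal(qv$median_cv[qv$run_id == "r1"], sd(rel_r1) / mean(rel_r1))
  # the CV of a protein whose peptide relative levels are (2, 4)
  expect_equal(sd(c(2, 4)) / mean(c(2, 4)), sqrt(2) / 3, tolerance = 1e-12)
})

test_that("protein CV is zero for identical peptides and NA when underpowered", {
  tab <- toy_table(seq = c("AK", "BK", "AK", "BK"),
                   run = c("r1", "r1", "r2", "r2"), ms1 = c(10, 10, 30, 30))
  qv <- quant_variability(tab, min_peptides = 2)
  expect_equal(qv$median_cv, c(0, 0))
  qv3 <- quant_variability(tab, min_peptides = 3)
  expect_true(all(is.na(qv3$median_cv)))
  expect_equal(qv3$n_proteins, c(0L, 0L))
})

test_that("protein CV is invariant to global per-cell intensity scaling", {
  set.seed(8)
  n <- 40
  tab <- toy_table(seq = rep(paste0("S", 1:20, "K"), 2),
                   run = rep(c("r1", "r2"), each = 20),
                   protein = rep(rep(c("P1", "P2", "P3", "P4"), each = 5), 2),
                   ms1 = rlnorm(n, 5, 1))
  scaled <- tab
  scaled$ms1_intensity[scaled$run_id == "r2"] <-
    scaled$ms1_intensity[scaled$run_id == "r2"] * 50
  expect_equal(quant_variability(tab, 3)$median_cv,
               quant_variability(scaled, 3)$median_cv)
})

test_that("intensity histograms shift by one decade under a 10x scale", {
  tab <- toy_table(seq = paste0(LETTERS[1:10], "K"),
                   channel = rep(c("d0", "d4"), each = 5),
                   ms1 = c(10^runif(5, 2, 4), 10^runif(5, 2, 4)))
  tab$ms1_intensity[tab$channel == "d4"] <-
    tab$ms1_intensity[tab$channel == "d0"] * 10
  h <- intensity_distribution(tab, bin_decades = 0.1)
  h0 <- h[h$group == "d0" & h$count > 0, ]
  h4 <- h[h$group == "d4" & h$count > 0, ]
  expect_equal(h4$bin_lower, h0$bin_lower + 1, tolerance = 1e-9)
  expect_equal(h4$count, h0$count)
})

test_that("log2 ratios are zero against self and +1 under doubling", {
  tab <- toy_table(seq = rep(paste0(LETTERS[1:6], "K"), 2),
                   run = rep(c("r1", "r2"), each = 6),
                   ms1 = c(1:6 * 100, 1:6 * 200))
  r <- ratio_distribution(tab, reference = "r1", by = "run")
  expect_equal(unname(r$medians["r2"]), 1)
  expect_equal(r$ratios$log2_ratio, rep(1, 6))
  same <- toy_table(seq = rep(paste0(LETTERS[1:6], "K"), 2),
                    run = rep(c("r1", "r2"), each = 6),
                    ms1 = rep(1:6 * 100, 2))
  expect_equal(unname(ratio_distribution(same, by = "run")$medians["r2"]), 0)
})

test_that("ratio distribution requires a shared precursor set", {
  tab <- toy_table(seq = c("AK", "BK"), run = c("r1", "r2"))
  expect_error(ratio_distribution(tab, by = "run"), "degenerate|shared")
})

test_that("identification counts split direct and translated IDs", {
  tab <- toy_table(seq = paste0(LETTERS[1:5], "K"),
                   translated = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  ic <- id_counts(tab, by = "channel", split_translated = TRUE)
  expect_equal(ic$counts$n, 5L)
  expect_equal(ic$counts$n_direct, 3L)
  expect_equal(ic$counts$n_translated, 2L)
})

test_that("protein-level counts include union and intersection", {
  tab <- toy_table(seq = paste0(LETTERS[1:4], "K"),
                   channel = c("d0", "d0", "d4", "d4"),
                   protein = c("a", "b", "b", "c"))
  pc <- id_counts(tab, by = "channel", level = "protein")
  expect_equal(pc$union, 3L)
  expect_equal(pc$intersection, 1L)
})

test_that("MS1-quantified fraction covers the boundary cases", {
  all_q <- toy_table(seq = paste0(LETTERS[1:4], "K"))
  expect_equal(ms1_quant_fraction(all_q)$fraction, 1)
  none <- toy_table(seq = paste0(LETTERS[1:4], "K"), ms1 = NA_real_)
  expect_equal(ms1_quant_fraction(none)$fraction, 0)
})

test_that("the FDR curve is monotone and saturates at the table size", {
  tab <- toy_table(seq = paste0(LETTERS[1:3], "K"), q = c(0.001, 0.005, 0.02))
  curve <- ids_vs_fdr(tab, thresholds = c(0.01, 1))
  expect_equal(curve$n_ids, c(2, 3))
  set.seed(12)
  tab2 <- toy_table(seq = paste0("S", 1:50, "K"), q = runif(50))
  curve2 <- ids_vs_fdr(tab2)
  expect_true(all(diff(curve2$n_ids) >= 0))
  expect_equal(curve2$n_ids[curve2$threshold == 1], 50)
})

test_that("per-window accumulation groups scans by isolation window", {
  st <- toy_scans(rt = c(0, 10, 20, 70, 80, 90), ms_level = c(1, 2, 2, 1, 2, 2),
                  it = c(5, 10, 251, 5, 10, 251), tic = 1,
                  center = c(NA, 440, 1000, NA, 440, 1000),
                  width = c(NA, 120, 800, NA, 120, 800))
  acc <- accumulation_by_window(st, rt_bin_s = 1000)
  expect_equal(nrow(acc), 2L)
  expect_equal(acc$mean_injection_ms[acc$isolation_center_mz == 440], 10)
  expect_equal(acc$mean_injection_ms[acc$isolation_center_mz == 1000], 251)

  flat <- toy_scans(rt = c(0, 1, 2, 3), ms_level = c(1, 2, 1, 2), it = 251,
                    tic = 1, center = c(NA, 700, NA, 700),
                    width = c(NA, 200, NA, 200))
  accf <- accumulation_by_window(flat, rt_bin_s = 60)
  expect_true(all(accf$mean_injection_ms == 251))
  # no MS2 scans -> empty frame, not an error
  ms1only <- toy_scans(rt = 0, ms_level = 1L, tic = 1)
  expect_equal(nrow(accumulation_by_window(ms1only)), 0L)
})

test_that("missing injection times are skipped in window means", {
  st <- toy_scans(rt = c(0, 1, 2), ms_level = c(1, 2, 2),
                  it = c(5, NA, 100), tic = 1,
                  center = c(NA, 700, 700), width = c(NA, 200, 200))
  acc <- accumulation_by_window(st, rt_bin_s = 1000)
  expect_equal(acc$mean_injection_ms, 100)
  expect_equal(acc$n_scans, 1L)
})

test_that("the ion map conserves total peak intensity and weights m/z", {
  st <- toy_scans(rt = c(5, 10), ms_level = c(1, 1),
                  peaks = list(peakdf(c(400, 600), c(1, 3)),
                               peakdf(c(500, 900), c(2, 2))))
  tm <- tic_map(st, rt_bin_s = 60, mz_bin_th = 10)
  expect_equal(sum(tm$intensity), 8)
  tr <- mean_mz_trace(st, rt_bin_s = 60)
  expect_equal(tr$mean_mz[1], (400 * 1 + 600 * 3 + 500 * 2 + 900 * 2) / 8)
  # a peak-free table is a precondition violation
  nopeaks <- toy_scans(rt = 0, ms_level = 1L, tic = 1)
  expect_error(tic_map(nopeaks), "peaks")
})

test_that("precursor S/N divides matched intensity by noise", {
  st <- toy_scans(rt = 10, ms_level = 1L,
                  peaks = list(peakdf(c(500, 600), c(500, 80), noise = 50)))
  tab <- toy_table(seq = "AK", mz = 500.001, rt = 10)
  expect_equal(precursor_sn(tab, st), 500 / 50, tolerance = 1e-6)
  # without noise values S/N is missing, not an error
  st2 <- toy_scans(rt = 10, ms_level = 1L,
                   peaks = list(peakdf(c(500, 600), c(500, 80))))
  expect_true(is.na(precursor_sn(tab, st2)))
  # no centroid within tolerance -> missing
  far <- toy_table(seq = "AK", mz = 505, rt = 10)
  expect_true(is.na(precursor_sn(far, st)))
})

test_that("simulated runs recover the configured noise floor S/N within 5%", {
  sim <- small_sim()
  cfg <- small_sim_cfg()
  tab <- sim$report[!is.na(sim$report$ms1_intensity), ]
  sn <- precursor_sn(tab, sim$scans)
  ok <- !is.na(sn)
  expect_gt(mean(ok), 0.5)
  # S/N should equal sampled intensity / configured peak noise
  expected <- tab$ms1_intensity[ok] * 0.6 / cfg$peak_noise   # monoisotope share
  expect_lt(median(abs(sn[ok] - expected) / expected), 0.05)
})
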