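# shared fixtures, built in code at test time

# small simulated run, memoised across test files
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(n_precursors = 80L, seed = 421L, run_duration_min = 12)
    cyc <- duty_cycle(equal_mz_windows(c(380, 1400), 4), max_injection_ms = 251)
    .fixture_env$sim <- simulate_run(cfg, cyc)
    .fixture_env$sim_cfg <- cfg
    .fixture_env$sim_cyc <- cyc
  }
  .fixture_env$sim
}
small_sim_cfg <- function() { small_sim(); .fixture_env$sim_cfg }
small_sim_cyc <- function() { small_sim(); .fixture_env$sim_cyc }

# hand-built precursor table from compact arguments
toy_table <- function(run = "r1", seq, charge = 2L, protein = "P1",
                      channel = "d0", ms1 = 100, ms2 = 100, q = 0.001,
                      rt = 600, translated = FALSE, mz = 500) {
  n <- max(length(seq), length(run), length(channel), length(ms1),
           length(protein), length(q), length(translated))
  seq <- rep_len(seq, n); channel <- rep_len(channel, n)
  # labelled sequences carry a channel tag, as real plexDIA reports do
  modified <- ifelse(channel == "unlabeled", seq,
                     paste0("(mTRAQ-K-", 4 * match(channel, c("d0", "d4", "d8"),
                                                   nomatch = 1) - 4, ")", seq))
  precursor_table(data.frame(
    run_id = rep_len(run, n), modified_sequence = modified,
    stripped_sequence = gsub("\\([^)]*\\)", "", seq),
    charge = rep_len(charge, n), precursor_mz = rep_len(mz, n),
    protein_group = rep_len(protein, n), rt_seconds = rep_len(rt, n),
    ms1_intensity = rep_len(ms1, n), ms2_intensity = rep_len(ms2, n),
    q_value = rep_len(q, n), channel = channel,
    translated = rep_len(translated, n), stringsAsFactors = FALSE))
}

# minimal scan table with attached peaks
toy_scans <- function(rt, ms_level, tic = NULL, it = 100,
                      center = NA_real_, width = NA_real_, peaks = NULL) {
  n <- length(rt)
  if (is.null(tic)) {
    tic <- vapply(seq_len(n), function(i) {
      if (!is.null(peaks) && !is.null(peaks[[i]])) sum(peaks[[i]]$intensity) else 0
    }, numeric(1))
  }
  scan_table(data.frame(scan_index = seq_len(n), ms_level = ms_level,
                        rt_seconds = rt, injection_time_ms = rep_len(it, n),
                        tic = tic, isolation_center_mz = rep_len(center, n),
                        isolation_width_mz = rep_len(width, n)),
             peaks = peaks)
}

peakdf <- function(mz, intensity, noise = NA_real_) {
  data.frame(mz = mz, intensity = intensity, noise = rep_len(noise, length(mz)))
}
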