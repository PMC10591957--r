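#' Piecewise-linear LC gradient profile
#'
#' @param breakpoints data.frame with `time_min` (non-decreasing) and
#'   `percent_b` in [0, 100]. The default is a 30-min active-gradient
#'   nanoflow profile: 4% B (min 0-2.5), 4-8% (2.5-3), 8-32% (3-33),
#'   32-95% (33-34), 95% (34-35), back to 4% and hold to min 53.
#' @param flow description string (informational).
#' @return a `gradient_profile`.
#' @export
gradient_profile <- function(breakpoints = data.frame(
                               time_min = c(0, 2.5, 3, 33, 34, 35, 35.1, 53),
                               percent_b = c(4, 4, 8, 32, 95, 95, 4, 4)),
                             flow = "200 nL/min") {
  stopifnot(all(diff(breakpoints$time_min) >= 0),
            all(breakpoints$percent_b >= 0 & breakpoints$percent_b <= 100))
  structure(list(breakpoints = breakpoints, flow = flow),
            class = "gradient_profile")
}

#' Mobile-phase composition at a gradient time point
#'
#' Linear interpolation between the profile's breakpoints.
#'
#' @param profile a [gradient_profile()].
#' @param t_min time in minutes, within the profile span.
#' @return percent buffer B.
#' @export
#' @examples
#' gradient_percent_b(gradient_profile(), 18)  # midpoint of the 8-32% ramp
gradient_percent_b <- function(profile, t_min) {
  bp <- profile$breakpoints
  if (any(t_min < min(bp$time_min) | t_min > max(bp$time_min))) {
    stop("time ", t_min[t_min < min(bp$time_min) | t_min > max(bp$time_min)][1],
         " min lies outside the gradient span [", min(bp$time_min), ", ",
         max(bp$time_min), "]")
  }
  stats::approx(bp$time_min, bp$percent_b, xout = t_min, ties = "ordered")$y
}

# first time (minutes) the rising gradient crosses a given %B
gradient_crossing_min <- function(profile, percent_b) {
  bp <- profile$breakpoints
  vapply(percent_b, function(b) {
    for (i in seq_len(nrow(bp) - 1L)) {
      if (bp$percent_b[i] <= b && bp$percent_b[i + 1L] >= b &&
          bp$percent_b[i + 1L] > bp$percent_b[i]) {
        return(bp$time_min[i] + (b - bp$percent_b[i]) /
                 (bp$percent_b[i + 1L] - bp$percent_b[i]) *
                 (bp$time_min[i + 1L] - bp$time_min[i]))
      }
    }
    NA_real_
  }, numeric(1))
}

#' Configuration of a synthetic 3-plex LC-MS run
#'
#' Describes the generative model of the simulator: precursors draw their m/z
#' from a two-component log-normal mixture with decreasing density over the
#' precursor range (so the lower m/z half is precursor-rich, as peptide
#' digests are), their abundance from a log-normal spanning several decades,
#' and their Gaussian elution width from a log-normal. Each precursor elutes
#' when the gradient crosses a per-precursor %B threshold (a hydrophobicity
#' surrogate drawn uniformly within the active ramp). Channels are mTRAQ
#' labels with a fixed +4.0071 Da per-label mass offset (one label site), a
#' relative abundance factor and a presence probability per channel.
#'
#' @param n_precursors number of distinct precursors.
#' @param mz_range precursor m/z range (Th).
#' @param mz_mix mixture parameters: `w1`, `meanlog1`, `sdlog1`, `meanlog2`,
#'   `sdlog2` (log-Th).
#' @param abundance_meanlog,abundance_sdlog log-normal apex-intensity model
#'   (charges per ms of ion flux).
#' @param sigma_meanlog,sigma_sdlog log-normal elution-width model (log-s).
#' @param gradient a [gradient_profile()].
#' @param elution_b_range %B interval within which precursors elute.
#' @param run_duration_min scheduled acquisition duration.
#' @param channels data.frame with `label` (`d0`/`d4`/`d8`), `factor`
#'   (relative abundance) and `presence` (per-precursor presence probability).
#' @param agc_target AGC target (charges).
#' @param max_injection_ms maximum accumulation time (ms).
#' @param noise_floor baseline ion flux (charges/ms) entering every scan.
#' @param peak_noise per-centroid noise estimate attached to simulated peaks.
#' @param lod per-scan sampled-intensity limit of detection.
#' @param interference_threshold minimum within-window flux share at apex for
#'   a direct MS2 identification.
#' @param id_slope,id_mid logistic detection model: the probability of a
#'   direct identification is `plogis(id_slope * (log10(SIR) - id_mid))`
#'   where SIR is the precursor's signal-to-interference ratio within its
#'   isolation window at apex. Identification probability therefore falls
#'   with spectral complexity.
#' @param translate_prob probability that a present-but-unidentified channel
#'   copy of an identified precursor is recovered by cross-channel
#'   translation.
#' @param seed mandatory RNG seed.
#' @return a `sim_config`.
#' @export
sim_config <- function(n_precursors = 500L,
                       mz_range = c(380, 1400),
                       mz_mix = list(w1 = 0.45, meanlog1 = log(560), sdlog1 = 0.20,
                                     meanlog2 = log(1000), sdlog2 = 0.22),
                       abundance_meanlog = log(3e5), abundance_sdlog = 1.15,
                       sigma_meanlog = log(2.2), sigma_sdlog = 0.6,
                       gradient = gradient_profile(),
                       elution_b_range = c(9, 31),
                       run_duration_min = 34,
                       channels = data.frame(label = c("d0", "d4", "d8"),
                                             factor = c(1, 1, 1),
                                             presence = c(1, 1, 1)),
                       agc_target = 3e6, max_injection_ms = 251,
                       noise_floor = 2000, peak_noise = 50,
                       lod = 1e5, interference_threshold = 0.01,
                       id_slope = 1.2, id_mid = -1.2,
                       translate_prob = 0.7, seed) {
  if (missing(seed)) stop("`seed` is mandatory for the simulator")
  stopifnot(all(channels$presence >= 0 & channels$presence <= 1),
            all(channels$label %in% c("d0", "d4", "d8")),
            n_precursors >= 0, mz_range[1] < mz_range[2])
  structure(as.list(environment()), class = "sim_config")
}

# truncated two-component log-normal mixture draw
draw_mz <- function(n, mix, range) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 10L)
    comp <- stats::runif(m) < mix$w1
    x <- ifelse(comp, stats::rlnorm(m, mix$meanlog1, mix$sdlog1),
                stats::rlnorm(m, mix$meanlog2, mix$sdlog2))
    out <- c(out, x[x >= range[1] & x < range[2]])
  }
  out[seq_len(n)]
}

random_sequences <- function(n) {
  aas <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]   # no K/R inside
  seqs <- vapply(seq_len(n), function(i) {
    paste0(paste(sample(aas, 6 + i %% 5, replace = TRUE), collapse = ""), "K")
  }, character(1))
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- vapply(dup, function(i) {
      paste0(paste(sample(aas, 6 + i %% 5, replace = TRUE), collapse = ""), "K")
    }, character(1))
  }
  seqs
}

#' Simulate a multiplexed LC-MS run
#'
#' Generates a full synthetic acquisition under `config` and the duty cycle
#' `cycle`: the scan schedule with per-scan injection times and TIC under the
#' AGC accumulation law (`injection = min(max IT, AGC target / ion flux)`),
#' MS1 centroid peaks (up to 3 isotopes per sampled precursor, spacing
#' 1.00335/z, above the per-scan LOD), and an emulated search report.
#'
#' The identification model is phenomenological: a channel precursor is
#' directly MS2-identified when its flux share within its isolation window at
#' apex exceeds the interference threshold (complex windows therefore yield
#' fewer identifications); present-but-missed channel copies of an identified
#' precursor become translated identifications with the configured
#' probability; q-values are drawn from a two-component mixture so that
#' FDR-threshold curves are informative. A precursor is MS1-quantified iff at
#' least one survey scan samples it above the LOD; its MS1 quantity is the
#' sampled peak height.
#'
#' @param config a [sim_config()].
#' @param cycle a [duty_cycle()].
#' @return list with `scans` (a [scan_table()] with peaks and noise),
#'   `report` (a `precursor_table` filtered at q = 0.01),
#'   `report_unfiltered` (data.frame in the DIA-NN report dialect) and
#'   `truth` (per channel-precursor ground truth).
#' @export
simulate_run <- function(config, cycle) {
  set.seed(config$seed)
  n <- config$n_precursors
  run_id <- paste0("sim_seed", config$seed)

  # --- precursor draws -------------------------------------------------
  if (n > 0L) {
    mz_mono <- draw_mz(n, config$mz_mix, config$mz_range)
    charge <- sample(c(2L, 3L), n, replace = TRUE, prob = c(0.8, 0.2))
    b_thr <- stats::runif(n, config$elution_b_range[1], config$elution_b_range[2])
    apex_s <- gradient_crossing_min(config$gradient, b_thr) * 60
    sigma <- stats::rlnorm(n, config$sigma_meanlog, config$sigma_sdlog)
    abund <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
    n_prot <- max(1L, n %/% 4L)
    protein <- paste0("PROT", formatC(sample.int(n_prot, n, replace = TRUE),
                                      width = 4, flag = "0"))
    seqs <- random_sequences(n)
  } else {
    mz_mono <- charge <- apex_s <- sigma <- abund <- numeric(0)
    protein <- seqs <- character(0)
    b_thr <- numeric(0)
  }

  ch <- config$channels
  label_k <- c(d0 = 0, d4 = 1, d8 = 2)
  cp <- do.call(rbind, lapply(seq_len(nrow(ch)), function(c) {
    if (n == 0L) return(NULL)
    data.frame(precursor = seq_len(n), channel = ch$label[c],
               present = stats::runif(n) < ch$presence[c],
               mz = mz_mono + 4.0071 * label_k[[ch$label[c]]] / charge,
               charge = charge, apex_s = apex_s, sigma = sigma,
               apex_intensity = abund * ch$factor[c],
               protein = protein, sequence = seqs)
  }))
  if (is.null(cp)) {
    cp <- data.frame(precursor = integer(), channel = character(),
                     present = logical(), mz = numeric(), charge = integer(),
                     apex_s = numeric(), sigma = numeric(),
                     apex_intensity = numeric(), protein = character(),
                     sequence = character())
  }
  cp$modified_sequence <- if (nrow(cp)) {
    paste0("(mTRAQ-K-", label_k[cp$channel] * 4, ")", cp$sequence)
  } else character(0)

  # --- scan schedule ---------------------------------------------------
  sched <- cycle_schedule(cycle)
  st_ms <- scan_time_ms(cycle)
  n_cycles <- max(1L, floor(config$run_duration_min * 60 * 1000 /
                              (nrow(sched) * st_ms)))
  slots <- nrow(sched)
  scan_level <- rep(sched$ms_level, n_cycles)
  scan_win <- rep(sched$window_index, n_cycles)
  scan_rt <- (rep((seq_len(n_cycles) - 1L) * slots, each = slots) +
                rep(sched$slot, n_cycles)) * st_ms / 1000
  nscan <- length(scan_rt)

  active_cp <- which(cp$present)
  gauss <- function(t, idx) {
    cp$apex_intensity[idx] * exp(-(t - cp$apex_s[idx])^2 / (2 * cp$sigma[idx]^2))
  }
  iso_frac <- c(0.6, 0.3, 0.1)
  scheme <- cycle$scheme
  win_of <- assign_window(scheme, cp$mz)

  injection <- numeric(nscan)
  tic <- numeric(nscan)
  peaks <- vector("list", nscan)
  iso_center <- rep(NA_real_, nscan)
  iso_width <- rep(NA_real_, nscan)
  ms1_scan_rts <- scan_rt[scan_level == 1L]

  for (i in seq_len(nscan)) {
    t <- scan_rt[i]
    idx <- active_cp[abs(t - cp$apex_s[active_cp]) <= 4 * cp$sigma[active_cp]]
    if (scan_level[i] == 1L) {
      inten <- if (length(idx)) gauss(t, idx) else numeric(0)
      flux <- sum(inten) + config$noise_floor
      injection[i] <- min(config$max_injection_ms, config$agc_target / flux)
      # centroids: up to 3 isotopes per sampled precursor above the LOD
      if (length(idx)) {
        mzs <- unlist(lapply(seq_along(idx), function(j) {
          cp$mz[idx[j]] + 1.00335 * (0:2) / cp$charge[idx[j]]
        }))
        ints <- unlist(lapply(seq_along(idx), function(j) inten[j] * iso_frac))
        keep <- ints >= config$lod
        if (any(keep)) {
          pk <- stats::aggregate(intensity ~ mz,
                                 data = data.frame(mz = mzs[keep],
                                                   intensity = ints[keep]),
                                 FUN = sum)
          pk <- pk[order(pk$mz), , drop = FALSE]
          rownames(pk) <- NULL
          pk$noise <- config$peak_noise
          peaks[[i]] <- pk
        }
      }
      tic[i] <- flux
    } else {
      w <- scan_win[i]
      iso_center[i] <- (scheme$lower_mz[w] + scheme$upper_mz[w]) / 2
      iso_width[i] <- scheme$width[w]
      widx <- idx[!is.na(win_of[idx]) & win_of[idx] == w]
      flux <- (if (length(widx)) sum(gauss(t, widx)) else 0) + config$noise_floor
      injection[i] <- min(config$max_injection_ms, config$agc_target / flux)
      tic[i] <- flux
    }
  }

  scans <- scan_table(
    data.frame(scan_index = seq_len(nscan), ms_level = scan_level,
               rt_seconds = scan_rt, injection_time_ms = injection, tic = tic,
               isolation_center_mz = iso_center, isolation_width_mz = iso_width),
    run_metadata(run_id = run_id, max_injection_ms = config$max_injection_ms,
                 resolving_power = cycle$resolving_power,
                 agc_target = config$agc_target,
                 precursor_range = config$mz_range),
    peaks = peaks)

  # --- identification emulation ---------------------------------------
  if (nrow(cp) > 0L) {
    # within-window flux share at apex (analytic, not at scan times)
    wflux <- vapply(seq_len(nrow(cp)), function(j) {
      if (!cp$present[j] || is.na(win_of[j])) return(NA_real_)
      w <- win_of[j]
      others <- which(cp$present & win_of == w)
      sum(gauss(cp$apex_s[j], others)) + config$noise_floor
    }, numeric(1))
    share <- ifelse(is.na(wflux), 0, cp$apex_intensity / wflux)
    cp$share_at_apex <- share
    # detection probability falls with spectral complexity: logistic in the
    # log signal-to-interference ratio within the isolation window
    sir <- ifelse(is.na(wflux), 0,
                  cp$apex_intensity /
                    pmax(wflux - cp$apex_intensity, config$noise_floor))
    p_detect <- stats::plogis(config$id_slope * (log10(pmax(sir, 1e-12)) -
                                                   config$id_mid))
    cp$identified_direct <- cp$present & share >= config$interference_threshold &
      stats::runif(nrow(cp)) < p_detect

    # MS1 quantification: best survey-scan sample above the LOD
    cp$ms1_height <- vapply(seq_len(nrow(cp)), function(j) {
      if (!cp$present[j]) return(NA_real_)
      near <- ms1_scan_rts[abs(ms1_scan_rts - cp$apex_s[j]) <= 4 * cp$sigma[j]]
      if (length(near) == 0L) return(NA_real_)
      h <- max(cp$apex_intensity[j] *
                 exp(-(near - cp$apex_s[j])^2 / (2 * cp$sigma[j]^2)))
      if (h * iso_frac[1] >= config$lod) h else NA_real_
    }, numeric(1))
    cp$ms1_quantified <- !is.na(cp$ms1_height)

    # translation: channel copies of an identified precursor
    direct_by_prec <- tapply(cp$identified_direct, cp$precursor, any)
    eligible <- cp$present & !cp$identified_direct &
      as.logical(direct_by_prec[as.character(cp$precursor)])
    cp$translated <- eligible & stats::runif(nrow(cp)) < config$translate_prob

    # q-value mixture: confident direct/translated IDs vs marginal rows
    cp$q_value <- NA_real_
    idd <- cp$identified_direct | cp$translated
    cp$q_value[idd] <- stats::runif(sum(idd), 0, 0.009)
    marginal <- cp$present & !idd & stats::runif(nrow(cp)) < 0.5
    cp$q_value[marginal] <- stats::runif(sum(marginal), 0.011, 0.6)
    cp$channel_q <- ifelse(cp$identified_direct, cp$q_value,
                           ifelse(!is.na(cp$q_value),
                                  pmax(cp$q_value, stats::runif(nrow(cp), 0.011, 0.6)),
                                  NA_real_))
    cp$translated_q <- ifelse(cp$translated, stats::runif(nrow(cp), 0, 0.009),
                              NA_real_)
  } else {
    cp$share_at_apex <- cp$ms1_height <- cp$q_value <- cp$channel_q <-
      cp$translated_q <- numeric(0)
    cp$identified_direct <- cp$ms1_quantified <- cp$translated <- logical(0)
  }

  emit <- cp[!is.na(cp$q_value), , drop = FALSE]
  report_unfiltered <- data.frame(
    Run = rep(run_id, nrow(emit)),
    Modified.Sequence = emit$modified_sequence,
    Stripped.Sequence = emit$sequence,
    Precursor.Charge = emit$charge,
    Precursor.Mz = emit$mz,
    Protein.Group = emit$protein,
    RT = emit$apex_s / 60,
    Ms1.Area = ifelse(emit$ms1_quantified, emit$ms1_height, 0),
    Precursor.Quantity = emit$apex_intensity * 0.5,
    Q.Value = emit$q_value,
    Channel.Q.Value = emit$channel_q,
    Translated.Q.Value = ifelse(is.na(emit$translated_q), "", emit$translated_q),
    stringsAsFactors = FALSE)

  tmp <- tempfile(fileext = ".tsv")
  utils::write.table(report_unfiltered, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  report <- read_report(tmp, q_threshold = 0.01)
  unlink(tmp)

  list(scans = scans, report = report, report_unfiltered = report_unfiltered,
       truth = cp)
}

#' Write a simulated bundle to disk
#'
#' @param sim output of [simulate_run()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; writes `scans.mzML`, `report.tsv` (unfiltered
#'   DIA-NN dialect) and `truth.tsv`.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mzml(sim$scans, file.path(dir, "scans.mzML"))
  utils::write.table(sim$report_unfiltered, file.path(dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
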