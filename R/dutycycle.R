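#' Orbitrap transient duration for a resolving-power setting
#'
#' The transient (image-current acquisition) time doubles with each doubling
#' of the resolving power. The default table covers the standard settings of
#' a benchtop Orbitrap; it can be overridden per instrument.
#'
#' @param resolving_power resolving power setting (at 200 m/z).
#' @param table named numeric vector mapping resolving power to transient ms.
#' @return transient duration in milliseconds.
#' @export
#' @examples
#' transient_ms(70000)  # 256 ms
transient_ms <- function(resolving_power,
                         table = c("17500" = 64, "35000" = 128,
                                   "70000" = 256, "140000" = 512)) {
  key <- as.character(resolving_power)
  if (!key %in% names(table)) {
    stop("unsupported resolving power ", resolving_power,
         "; known settings: ", paste(names(table), collapse = ", "))
  }
  unname(table[key])
}

#' Construct a duty-cycle specification
#'
#' A duty cycle is the repeating sequence of MS1 survey scans and MS2
#' fragmentation scans. Survey scans occupy the slots in `ms1_positions`
#' (0-based, within the cycle's scan sequence); the MS2 windows of `scheme`
#' fill the remaining slots in order.
#'
#' @param scheme a [window_scheme()]; its number of windows is the number of
#'   MS2 scans per cycle.
#' @param n_ms1 number of survey scans per cycle.
#' @param ms1_positions 0-based slot indices of the survey scans; default
#'   spreads them evenly over the cycle starting at slot 0.
#' @param resolving_power Orbitrap resolving power for all scans.
#' @param max_injection_ms maximum ion accumulation time (ms).
#' @param overhead_ms fixed per-scan overhead (ms), default 0.
#' @return a `duty_cycle` object.
#' @export
duty_cycle <- function(scheme, n_ms1 = 1L, ms1_positions = NULL,
                       resolving_power = 70000L, max_injection_ms = 300,
                       overhead_ms = 0) {
  n_ms2 <- nrow(scheme)
  total <- n_ms1 + n_ms2
  if (is.null(ms1_positions)) {
    ms1_positions <- floor(total * (seq_len(n_ms1) - 1L) / n_ms1)
  }
  ms1_positions <- as.integer(ms1_positions)
  if (length(ms1_positions) != n_ms1) stop("need one position per MS1 scan")
  if (any(diff(ms1_positions) <= 0)) stop("MS1 positions must be strictly increasing")
  if (any(ms1_positions < 0L | ms1_positions >= total)) {
    stop("MS1 positions must lie within [0, ", total, ")")
  }
  structure(list(scheme = scheme, n_ms1 = as.integer(n_ms1),
                 ms1_positions = ms1_positions,
                 resolving_power = as.integer(resolving_power),
                 max_injection_ms = max_injection_ms, overhead_ms = overhead_ms),
            class = "duty_cycle")
}

#' @export
print.duty_cycle <- function(x, ...) {
  cat(sprintf("Duty cycle: %d MS1 + %d MS2 scans, RP %d, max IT %g ms\n",
              x$n_ms1, nrow(x$scheme), x$resolving_power, x$max_injection_ms))
  cat(sprintf("  scan time %g ms, cycle %g s, MS1 sampling interval %g s\n",
              scan_time_ms(x), cycle_time_s(x), ms1_sampling_interval_s(x)))
  invisible(x)
}

#' Per-scan duration under the parallelised accumulation model
#'
#' Ion accumulation runs in parallel with the previous scan's transient, so a
#' scan takes the longer of the two, plus any fixed overhead. MS1 and MS2
#' scans at the same settings take the same time.
#'
#' @param spec a [duty_cycle()].
#' @return scan duration in milliseconds.
#' @export
scan_time_ms <- function(spec) {
  max(transient_ms(spec$resolving_power), spec$max_injection_ms) + spec$overhead_ms
}

#' Duty-cycle duration
#'
#' Total duration of one cycle: (number of MS1 + MS2 scans) times the per-scan
#' time. Linear in the scan count — each added MS2 window costs exactly one
#' scan time.
#'
#' @param spec a [duty_cycle()].
#' @return cycle duration in seconds.
#' @export
#' @examples
#' # 1 survey + 2 MS2 scans at 70k / 300 ms: 0.9 s per cycle
#' cycle_time_s(duty_cycle(equal_mz_windows(c(380, 1400), 2)))
cycle_time_s <- function(spec) {
  (spec$n_ms1 + nrow(spec$scheme)) * scan_time_ms(spec) / 1000
}

#' MS1-to-MS1 precursor sampling interval
#'
#' The longest wait between consecutive survey scans, computed as the maximum
#' gap between MS1 slots across the cycle wrap-around. With a single survey
#' scan this equals the cycle time; evenly distributed survey scans divide the
#' cycle by their count.
#'
#' @param spec a [duty_cycle()].
#' @return maximum MS1 sampling interval in seconds.
#' @export
ms1_sampling_interval_s <- function(spec) {
  total <- spec$n_ms1 + nrow(spec$scheme)
  pos <- sort(spec$ms1_positions)
  gaps <- if (length(pos) == 1L) total else diff(c(pos, pos[1] + total))
  max(gaps) * scan_time_ms(spec) / 1000
}

#' Fraction of the elution apex captured by discrete sampling
#'
#' A Gaussian elution peak sampled on a grid of spacing `interval_s` is seen
#' at most at `exp(-d^2 / (2 sigma^2))` of its apex intensity, where `d` is
#' the distance from the apex to the nearest sample. With the sampling phase
#' uniform, `d` is uniform on `[0, interval/2]`, so the median loss
#' corresponds to `d = interval/4`.
#'
#' @param peak list with `sigma_s` (Gaussian SD, seconds); see [elution_peak()].
#' @param interval_s sampling interval (s).
#' @param phase numeric grid offset in seconds (0 samples the apex exactly),
#'   or `"median"` for the median over a uniform phase.
#' @return fraction of the apex intensity captured, in (0, 1].
#' @export
apex_sampling_ratio <- function(peak, interval_s, phase = "median") {
  stopifnot(interval_s > 0)
  d <- if (identical(phase, "median")) {
    interval_s / 4
  } else {
    off <- phase %% interval_s
    min(off, interval_s - off)
  }
  exp(-d^2 / (2 * peak$sigma_s^2))
}

#' A Gaussian elution-peak description
#'
#' @param sigma_s Gaussian SD of the elution profile (seconds).
#' @param apex_rt_s apex retention time (seconds).
#' @param apex_intensity apex intensity.
#' @return list of class `elution_peak`.
#' @export
elution_peak <- function(sigma_s, apex_rt_s = 0, apex_intensity = 1) {
  stopifnot(sigma_s > 0, apex_intensity > 0)
  structure(list(sigma_s = sigma_s, apex_rt_s = apex_rt_s,
                 apex_intensity = apex_intensity), class = "elution_peak")
}

#' Data points collected per elution peak
#'
#' Number of duty cycles that fit into the peak's base width, taken as four
#' Gaussian SDs.
#'
#' @param peak an [elution_peak()].
#' @param cycle_s duty-cycle duration (s).
#' @return expected samples per peak (real).
#' @export
points_per_peak <- function(peak, cycle_s) {
  stopifnot(cycle_s > 0)
  4 * peak$sigma_s / cycle_s
}

#' Scan-by-scan schedule of one duty cycle
#'
#' @param spec a [duty_cycle()].
#' @return data.frame with `slot` (0-based), `ms_level`, `window_index`
#'   (`NA` for MS1), `start_ms` and `end_ms` relative to the cycle start.
#' @export
cycle_schedule <- function(spec) {
  total <- spec$n_ms1 + nrow(spec$scheme)
  st <- scan_time_ms(spec)
  level <- rep(2L, total)
  level[spec$ms1_positions + 1L] <- 1L
  win <- rep(NA_integer_, total)
  win[level == 2L] <- seq_len(nrow(spec$scheme))
  data.frame(slot = seq_len(total) - 1L, ms_level = level, window_index = win,
             start_ms = (seq_len(total) - 1L) * st, end_ms = seq_len(total) * st)
}
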