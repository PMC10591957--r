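#' Detect peptide-like features on centroided MS1 scans
#'
#' A deliberately simple trace-based feature finder: centroids in consecutive
#' MS1 scans within `ppm_tol` of a trace's running median m/z are chained
#' greedily; a trace survives a single missed scan (one-scan gap tolerance)
#' and is kept when it spans at least `min_scans` scans. The apex is the most
#' intense scan of the trace. With `isotope_check`, a coeluting trace offset
#' by +1.00335/z (z in 1..4) within `ppm_tol` assigns the charge and counts as
#' an isotope; traces without such a partner get charge 0 (unknown).
#'
#' This is a minimal stand-in for a full isotope-pattern feature finder such
#' as Dinosaur: it builds single-trace features without isotope-pattern
#' scoring or hill splitting, which is sufficient for scan-schedule QC
#' (feature counts, elution lengths) but not for quantification.
#'
#' @param scans a [scan_table()] with MS1 peaks loaded.
#' @param ppm_tol chaining tolerance in ppm (default 10).
#' @param min_scans minimum scans per trace (default 3).
#' @param isotope_check look for +1.00335/z partner traces (default TRUE).
#' @return data.frame of features: `mz_mono`, `charge`, `rt_start_s`,
#'   `rt_apex_s`, `rt_end_s`, `apex_intensity`, `n_isotopes`, `n_scans`.
#' @export
detect_features <- function(scans, ppm_tol = 10, min_scans = 3L,
                            isotope_check = TRUE) {
  if (is.null(scans$peaks)) stop("MS1 peaks must be loaded for feature detection")
  s <- scans$scans
  ms1 <- which(s$ms_level == 1L)
  empty <- data.frame(mz_mono = numeric(), charge = integer(),
                      rt_start_s = numeric(), rt_apex_s = numeric(),
                      rt_end_s = numeric(), apex_intensity = numeric(),
                      n_isotopes = integer(), n_scans = integer())
  if (length(ms1) < min_scans) return(empty)

  # active traces: lists of (mzs, ints, rts, gap)
  active <- list()
  finished <- list()
  for (i in ms1) {
    p <- scans$peaks[[i]]
    rt <- s$rt_seconds[i]
    pmz <- if (!is.null(p)) p$mz else numeric(0)
    pint <- if (!is.null(p)) p$intensity else numeric(0)
    used <- rep(FALSE, length(pmz))
    keep <- logical(length(active))
    for (k in seq_along(active)) {
      tr <- active[[k]]
      med <- stats::median(tr$mzs)
      tol <- med * ppm_tol * 1e-6
      cand <- which(!used & abs(pmz - med) <= tol)
      if (length(cand) > 0L) {
        j <- cand[which.min(abs(pmz[cand] - med))]
        used[j] <- TRUE
        tr$mzs <- c(tr$mzs, pmz[j]); tr$ints <- c(tr$ints, pint[j])
        tr$rts <- c(tr$rts, rt); tr$gap <- 0L
        active[[k]] <- tr
        keep[k] <- TRUE
      } else if (tr$gap == 0L) {
        tr$gap <- 1L             # tolerate one missed scan
        active[[k]] <- tr
        keep[k] <- TRUE
      } else {
        finished[[length(finished) + 1L]] <- tr
      }
    }
    active <- active[keep]
    for (j in which(!used)) {
      active[[length(active) + 1L]] <- list(mzs = pmz[j], ints = pint[j],
                                            rts = rt, gap = 0L)
    }
  }
  finished <- c(finished, active)
  finished <- Filter(function(tr) length(tr$rts) >= min_scans, finished)
  if (length(finished) == 0L) return(empty)

  feats <- do.call(rbind, lapply(finished, function(tr) {
    apex <- which.max(tr$ints)
    data.frame(mz_mono = stats::median(tr$mzs), charge = 0L,
               rt_start_s = min(tr$rts), rt_apex_s = tr$rts[apex],
               rt_end_s = max(tr$rts), apex_intensity = tr$ints[apex],
               n_isotopes = 1L, n_scans = length(tr$rts))
  }))
  feats <- feats[order(feats$mz_mono), , drop = FALSE]
  rownames(feats) <- NULL

  if (isotope_check && nrow(feats) > 1L) {
    for (i in seq_len(nrow(feats))) {
      for (z in 1:4) {
        target <- feats$mz_mono[i] + 1.00335 / z
        tol <- target * ppm_tol * 1e-6
        partner <- which(abs(feats$mz_mono - target) <= tol &
                           feats$rt_start_s <= feats$rt_apex_s[i] &
                           feats$rt_end_s >= feats$rt_apex_s[i])
        if (length(partner) > 0L) {
          feats$charge[i] <- z
          feats$n_isotopes[i] <- feats$n_isotopes[i] + 1L
          # extend along the envelope
          nxt <- target + 1.00335 / z
          while (any(abs(feats$mz_mono - nxt) <= nxt * ppm_tol * 1e-6 &
                       feats$rt_start_s <= feats$rt_apex_s[i] &
                       feats$rt_end_s >= feats$rt_apex_s[i])) {
            feats$n_isotopes[i] <- feats$n_isotopes[i] + 1L
            nxt <- nxt + 1.00335 / z
          }
          break
        }
      }
    }
  }
  feats
}

#' Summarise detected features against identified precursors
#'
#' Reports the feature count, features per retention-time bin, the
#' elution-length (at base: trace RT span) histogram, and the fraction of
#' features matched to an identified precursor (m/z within `ppm_tol` of the
#' precursor m/z and apex RT within the precursor's elution window).
#' Unmatched features flag ion clusters not assigned a sequence —
#' contaminants, singly charged species, or peptides missed by the search.
#'
#' @param features output of [detect_features()].
#' @param table optional `precursor_table` for matching.
#' @param rt_bin_s retention-time bin width (s), default 60.
#' @param ppm_tol m/z matching tolerance (ppm), default 10.
#' @param rt_tol_s RT matching half-window around the feature span (s),
#'   default 10.
#' @return list with `n_features`, `by_rt` (data.frame), `elution_lengths`
#'   (numeric vector, seconds) and, when `table` is given, `matched_fraction`.
#' @export
feature_summary <- function(features, table = NULL, rt_bin_s = 60,
                            ppm_tol = 10, rt_tol_s = 10) {
  out <- list(n_features = nrow(features))
  out$elution_lengths <- features$rt_end_s - features$rt_start_s
  if (nrow(features) > 0L) {
    edges <- seq(0, max(features$rt_apex_s) + rt_bin_s, by = rt_bin_s)
    bin <- findInterval(features$rt_apex_s, edges, rightmost.closed = FALSE)
    out$by_rt <- data.frame(rt_bin_lower = edges[-length(edges)],
                            rt_bin_upper = edges[-1],
                            n_features = tabulate(bin, nbins = length(edges) - 1L))
  } else {
    out$by_rt <- data.frame(rt_bin_lower = numeric(), rt_bin_upper = numeric(),
                            n_features = integer())
  }
  if (!is.null(table) && nrow(features) > 0L) {
    pm <- table$precursor_mz; prt <- table$rt_seconds
    ok <- !is.na(pm)
    matched <- vapply(seq_len(nrow(features)), function(i) {
      tol <- features$mz_mono[i] * ppm_tol * 1e-6
      any(ok & abs(pm - features$mz_mono[i]) <= tol &
            prt >= features$rt_start_s[i] - rt_tol_s &
            prt <= features$rt_end_s[i] + rt_tol_s)
    }, logical(1))
    out$matched_fraction <- mean(matched)
  }
  out
}

#' Write a feature table in a Dinosaur-style layout
#'
#' @param features output of [detect_features()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  out <- data.frame(mz = features$mz_mono, charge = features$charge,
                    rtStart = features$rt_start_s / 60,
                    rtApex = features$rt_apex_s / 60,
                    rtEnd = features$rt_end_s / 60,
                    intensityApex = features$apex_intensity,
                    nIsotopes = features$n_isotopes, nScans = features$n_scans)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Dinosaur-style feature TSV
#'
#' Accepts the column layout of [write_features()] (RT columns in minutes),
#' so an externally produced feature table can replace [detect_features()]
#' output in [feature_summary()].
#'
#' @param path feature TSV path.
#' @return data.frame in the [detect_features()] layout.
#' @export
read_features <- function(path) {
  d <- utils::read.delim(path, sep = "\t")
  needed <- c("mz", "charge", "rtStart", "rtApex", "rtEnd", "intensityApex",
              "nIsotopes", "nScans")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols) > 0L) {
    stop("feature file is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  data.frame(mz_mono = d$mz, charge = as.integer(d$charge),
             rt_start_s = d$rtStart * 60, rt_apex_s = d$rtApex * 60,
             rt_end_s = d$rtEnd * 60, apex_intensity = d$intensityApex,
             n_isotopes = as.integer(d$nIsotopes), n_scans = as.integer(d$nScans))
}
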