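#' Jaccard index between two identification sets
#'
#' Data completeness between two channels or runs of a plexDIA set is the
#' Jaccard index |A intersect B| / |A union B| of their identification sets.
#' Two empty sets are defined as fully complete (J = 1), with a warning.
#'
#' @param ids_a,ids_b vectors of identification keys.
#' @return Jaccard index in [0, 1].
#' @export
jaccard_completeness <- function(ids_a, ids_b) {
  a <- unique(ids_a); b <- unique(ids_b)
  if (length(a) == 0L && length(b) == 0L) {
    warning("both identification sets are empty; completeness defined as 1")
    return(1)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise data-completeness matrix
#'
#' Computes the Jaccard completeness for all pairwise comparisons of the
#' identification sets of a plexDIA table, grouped by channel or by run, at
#' precursor or protein level.
#'
#' @param table a `precursor_table`.
#' @param by grouping: `"channel"` or `"run"`.
#' @param id_key identification level: `"precursor"` (modified sequence +
#'   charge) or `"protein"` (protein group).
#' @return symmetric matrix of Jaccard indices with unit diagonal, one
#'   row/column per group.
#' @export
completeness_matrix <- function(table, by = c("channel", "run"),
                                id_key = c("precursor", "protein")) {
  by <- match.arg(by); id_key <- match.arg(id_key)
  grp <- if (by == "channel") table$channel else table$run_id
  # across channels a precursor is the same peptide with a different label
  # tag, so channel comparisons key on the stripped sequence
  ids <- if (id_key == "precursor") {
    seqs <- if (by == "channel") table$stripped_sequence else table$modified_sequence
    paste(seqs, table$charge, sep = "/")
  } else table$protein_group
  groups <- sort(unique(grp))
  if (length(groups) < 2L) stop("completeness needs at least two groups")
  sets <- lapply(groups, function(g) unique(ids[grp == g]))
  n <- length(groups)
  J <- matrix(1, n, n, dimnames = list(groups, groups))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    J[i, j] <- J[j, i] <- jaccard_completeness(sets[[i]], sets[[j]])
  }
  J
}

#' Quantification variability between peptides of the same protein
#'
#' A single-proteome quality metric: for each cell (run x channel), the
#' median over proteins of the coefficient of variation between that
#' protein's peptides. Intensities are first collapsed to peptide level
#' (stripped sequence; charge states summed), each cell is normalized by its
#' median peptide intensity (which makes the metric exactly invariant to
#' global per-cell scaling, e.g. differing sample amounts), and each peptide
#' is then expressed relative to its mean across cells to remove
#' peptide-specific ionization efficiency. The CV uses the sample SD (n - 1);
#' only proteins with at least `min_peptides` distinct peptides in a cell
#' contribute.
#'
#' @param table a `precursor_table` with MS1 intensities.
#' @param min_peptides minimum distinct peptides per protein (default 3).
#' @param intensity which quantity to use: `"ms1"` (default) or `"ms2"`.
#' @return data.frame with `run_id`, `channel`, `median_cv`, `n_proteins`;
#'   `median_cv` is `NA` where no protein passes the filter.
#' @export
quant_variability <- function(table, min_peptides = 3L,
                              intensity = c("ms1", "ms2")) {
  intensity <- match.arg(intensity)
  val <- if (intensity == "ms1") table$ms1_intensity else table$ms2_intensity
  keep <- !is.na(val) & val > 0
  d <- data.frame(cell = paste(table$run_id, table$channel, sep = "\r"),
                  run_id = table$run_id, channel = table$channel,
                  protein = table$protein_group,
                  peptide = table$stripped_sequence, value = val)[keep, ]
  cells <- unique(d[, c("cell", "run_id", "channel")])
  cells <- cells[order(cells$cell), , drop = FALSE]
  if (nrow(d) == 0L) {
    return(data.frame(run_id = character(), channel = character(),
                      median_cv = numeric(), n_proteins = integer()))
  }
  # collapse charge states: sum per (cell, protein, peptide)
  agg <- stats::aggregate(value ~ cell + protein + peptide, data = d, FUN = sum)
  # per-cell median normalization: removes global loading/scale differences
  cell_med <- tapply(agg$value, agg$cell, stats::median)
  agg$value <- agg$value / as.numeric(cell_med[agg$cell])
  # relative level: divide by the peptide's mean across cells
  pep_key <- paste(agg$protein, agg$peptide, sep = "\r")
  pep_mean <- tapply(agg$value, pep_key, mean)
  agg$rel <- agg$value / as.numeric(pep_mean[pep_key])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- agg[agg$cell == cells$cell[i], , drop = FALSE]
    cvs <- tapply(sub$rel, sub$protein, function(r) {
      if (length(r) < min_peptides) return(NA_real_)
      stats::sd(r) / mean(r)
    })
    cvs <- cvs[!is.na(cvs)]
    data.frame(run_id = cells$run_id[i], channel = cells$channel[i],
               median_cv = if (length(cvs)) stats::median(cvs) else NA_real_,
               n_proteins = length(cvs))
  })
  do.call(rbind, out)
}

#' Per-channel precursor intensity distributions
#'
#' Histogram of log10 precursor intensities for each plexDIA channel, on a
#' fixed decade grid (default 0.1-decade bins). Useful for spotting failed
#' channels/cells by their shifted intensity distribution.
#'
#' @param table a `precursor_table`.
#' @param by_channel group by channel (`TRUE`, default) or by run.
#' @param intensity `"ms1"` (default) or `"ms2"` quantities.
#' @param bin_decades histogram bin width in decades.
#' @return data.frame with `group`, `bin_lower`, `bin_upper` (log10 units)
#'   and `count`.
#' @export
intensity_distribution <- function(table, by_channel = TRUE,
                                   intensity = c("ms1", "ms2"),
                                   bin_decades = 0.1) {
  intensity <- match.arg(intensity)
  val <- if (intensity == "ms1") table$ms1_intensity else table$ms2_intensity
  grp <- if (by_channel) table$channel else table$run_id
  keep <- !is.na(val) & val > 0
  lv <- log10(val[keep]); grp <- grp[keep]
  if (length(lv) == 0L) {
    return(data.frame(group = character(), bin_lower = numeric(),
                      bin_upper = numeric(), count = integer()))
  }
  lo <- floor(min(lv) / bin_decades) * bin_decades
  hi <- ceiling(max(lv) / bin_decades) * bin_decades
  edges <- seq(lo, hi + bin_decades / 2, by = bin_decades)
  out <- lapply(sort(unique(grp)), function(g) {
    idx <- findInterval(lv[grp == g], edges, rightmost.closed = FALSE)
    data.frame(group = g, bin_lower = edges[-length(edges)],
               bin_upper = edges[-1],
               count = tabulate(idx, nbins = length(edges) - 1L))
  })
  do.call(rbind, out)
}

#' Log2 intensity ratios relative to a reference group
#'
#' For precursors identified in all compared groups (runs or channels), the
#' per-group log2 ratio of intensity to the reference group. The median ratio
#' drops when a method samples elution apexes poorly, which is the signature
#' of too-long duty cycles.
#'
#' @param table a `precursor_table`.
#' @param reference reference group label (default: first group).
#' @param by compare `"run"`s (default) or `"channel"`s.
#' @param intensity `"ms1"` (default) or `"ms2"`.
#' @return list with `ratios` (data.frame `group`, `precursor`, `log2_ratio`)
#'   and `medians` (named numeric, median log2 ratio per group).
#' @export
ratio_distribution <- function(table, reference = NULL, by = c("run", "channel"),
                               intensity = c("ms1", "ms2")) {
  by <- match.arg(by); intensity <- match.arg(intensity)
  val <- if (intensity == "ms1") table$ms1_intensity else table$ms2_intensity
  grp <- if (by == "run") table$run_id else table$channel
  # cross-channel comparisons strip the label tag from the precursor key
  key <- if (by == "channel") {
    paste(table$stripped_sequence, table$charge, sep = "/")
  } else {
    paste(table$modified_sequence, table$charge, table$channel, sep = "/")
  }
  keep <- !is.na(val) & val > 0
  grp <- grp[keep]; key <- key[keep]; val <- val[keep]
  groups <- unique(grp)
  if (length(groups) < 2L) stop("ratio distribution needs at least two groups")
  if (is.null(reference)) reference <- groups[1]
  if (!reference %in% groups) stop("reference group '", reference, "' not found")
  # precursors identified across all conditions
  common <- Reduce(intersect, lapply(groups, function(g) key[grp == g]))
  if (length(common) == 0L) stop("degenerate input: no precursor is shared by all groups")
  lookup <- function(g) {
    v <- val[grp == g]; k <- key[grp == g]
    as.numeric(tapply(v, k, max)[common])   # guard duplicate keys
  }
  ref_val <- lookup(reference)
  ratios <- do.call(rbind, lapply(setdiff(groups, reference), function(g) {
    data.frame(group = g, precursor = common,
               log2_ratio = log2(lookup(g) / ref_val))
  }))
  medians <- tapply(ratios$log2_ratio, ratios$group, stats::median)
  list(ratios = ratios, medians = medians)
}

#' Identification counts per run or channel
#'
#' Distinct identifications per group, optionally split into direct versus
#' translated (cross-channel propagated) identifications, at precursor or
#' protein level. At protein level the intersection across groups and the
#' union over all groups are reported alongside.
#'
#' @param table a `precursor_table`.
#' @param by `"run"` or `"channel"`.
#' @param split_translated report direct and translated counts separately.
#' @param level `"precursor"` or `"protein"`.
#' @param ms1_only count only records quantified at the MS1 level.
#' @return list with `counts` (data.frame `group`, `n`, and when split
#'   `n_direct`/`n_translated`) and, at protein level, `intersection` and
#'   `union` counts across groups.
#' @export
id_counts <- function(table, by = c("run", "channel"), split_translated = FALSE,
                      level = c("precursor", "protein"), ms1_only = FALSE) {
  by <- match.arg(by); level <- match.arg(level)
  t <- as.data.frame(table)
  if (ms1_only) t <- t[!is.na(t$ms1_intensity), , drop = FALSE]
  grp <- if (by == "run") t$run_id else t$channel
  ids <- if (level == "precursor") {
    seqs <- if (by == "channel") t$stripped_sequence else t$modified_sequence
    paste(seqs, t$charge, sep = "/")
  } else t$protein_group
  groups <- sort(unique(grp))
  counts <- do.call(rbind, lapply(groups, function(g) {
    sel <- grp == g
    row <- data.frame(group = g, n = length(unique(ids[sel])))
    if (split_translated) {
      row$n_direct <- length(unique(ids[sel & !t$translated]))
      row$n_translated <- length(setdiff(unique(ids[sel & t$translated]),
                                         unique(ids[sel & !t$translated])))
    }
    row
  }))
  out <- list(counts = counts)
  if (level == "protein" && length(groups) >= 2L) {
    sets <- lapply(groups, function(g) unique(ids[grp == g]))
    out$intersection <- length(Reduce(intersect, sets))
    out$union <- length(Reduce(union, sets))
  }
  out
}

#' Fraction of precursors quantified at the MS1 level
#'
#' Identified precursors lacking an MS1 quantity were never sampled above the
#' detection limit by a survey scan; their fraction drops as duty cycles
#' lengthen and rises with additional survey scans.
#'
#' @param table a `precursor_table`.
#' @param by `"run"` (default) or `"channel"`.
#' @return data.frame with `group`, `n_records`, `n_ms1`, `fraction`.
#' @export
ms1_quant_fraction <- function(table, by = c("run", "channel")) {
  by <- match.arg(by)
  grp <- if (by == "run") table$run_id else table$channel
  groups <- sort(unique(grp))
  do.call(rbind, lapply(groups, function(g) {
    sel <- grp == g
    n <- sum(sel); nq <- sum(sel & !is.na(table$ms1_intensity))
    data.frame(group = g, n_records = n, n_ms1 = nq,
               fraction = if (n > 0L) nq / n else NA_real_)
  }))
}

#' Identifications as a function of the FDR threshold
#'
#' Cumulative count of records passing each q-value threshold of a grid;
#' non-decreasing in the threshold, reaching the table size at q = 1.
#' Must be fed an unfiltered table (q-values intact).
#'
#' @param table a `precursor_table` with q-values.
#' @param thresholds numeric grid of q-value thresholds.
#' @return data.frame with `threshold` and `n_ids`.
#' @export
ids_vs_fdr <- function(table, thresholds = c(0.001, 0.002, 0.005, 0.01, 0.02,
                                             0.05, 0.1, 0.5, 1)) {
  q <- table$q_value
  data.frame(threshold = thresholds,
             n_ids = vapply(thresholds, function(t) sum(q <= t, na.rm = TRUE),
                            numeric(1)))
}

#' Mean MS2 accumulation time per window across the gradient
#'
#' Groups MS2 scans by their isolation window (center, width) and reports the
#' mean ion injection time per retention-time bin per window. Windows that
#' fill to the AGC target in a few milliseconds sit far below the maximum
#' accumulation time; sparse windows sit at the ceiling.
#'
#' @param scans a [scan_table()].
#' @param rt_bin_s retention-time bin width (s), default 60.
#' @return data.frame with `window_index`, `isolation_center_mz`,
#'   `isolation_width_mz`, `rt_bin_lower`, `rt_bin_upper`,
#'   `mean_injection_ms`, `n_scans`. Empty when the run has no MS2 scans.
#' @export
accumulation_by_window <- function(scans, rt_bin_s = 60) {
  s <- scans$scans
  ms2 <- s[s$ms_level == 2L & !is.na(s$isolation_center_mz), , drop = FALSE]
  if (nrow(ms2) == 0L) {
    return(data.frame(window_index = integer(), isolation_center_mz = numeric(),
                      isolation_width_mz = numeric(), rt_bin_lower = numeric(),
                      rt_bin_upper = numeric(), mean_injection_ms = numeric(),
                      n_scans = integer()))
  }
  wkey <- paste(ms2$isolation_center_mz, ms2$isolation_width_mz, sep = "\r")
  wins <- unique(data.frame(key = wkey, center = ms2$isolation_center_mz,
                            width = ms2$isolation_width_mz))
  wins <- wins[order(wins$center), , drop = FALSE]
  edges <- seq(0, max(s$rt_seconds) + rt_bin_s, by = rt_bin_s)
  bin <- findInterval(ms2$rt_seconds, edges, rightmost.closed = FALSE)
  out <- lapply(seq_len(nrow(wins)), function(w) {
    sel <- wkey == wins$key[w]
    res <- lapply(sort(unique(bin[sel])), function(b) {
      it <- ms2$injection_time_ms[sel & bin == b]
      data.frame(window_index = w, isolation_center_mz = wins$center[w],
                 isolation_width_mz = wins$width[w],
                 rt_bin_lower = edges[b], rt_bin_upper = edges[b + 1L],
                 mean_injection_ms = mean(it, na.rm = TRUE),
                 n_scans = sum(!is.na(it)))
    })
    do.call(rbind, res)
  })
  res <- do.call(rbind, out)
  res$mean_injection_ms[is.nan(res$mean_injection_ms)] <- NA_real_
  res
}

#' Mean MS1 accumulation time across the gradient
#'
#' @param scans a [scan_table()].
#' @param rt_bin_s retention-time bin width (s), default 60.
#' @return data.frame with `rt_bin_lower`, `rt_bin_upper`,
#'   `mean_injection_ms`, `n_scans`.
#' @export
ms1_accumulation <- function(scans, rt_bin_s = 60) {
  s <- scans$scans
  ms1 <- s[s$ms_level == 1L, , drop = FALSE]
  edges <- seq(0, max(c(s$rt_seconds, 0)) + rt_bin_s, by = rt_bin_s)
  bin <- findInterval(ms1$rt_seconds, edges, rightmost.closed = FALSE)
  do.call(rbind, lapply(sort(unique(bin)), function(b) {
    it <- ms1$injection_time_ms[bin == b]
    data.frame(rt_bin_lower = edges[b], rt_bin_upper = edges[b + 1L],
               mean_injection_ms = if (all(is.na(it))) NA_real_ else mean(it, na.rm = TRUE),
               n_scans = sum(!is.na(it)))
  }))
}

#' TIC ion map over retention time and m/z
#'
#' Sums MS1 centroid intensity into a retention-time x m/z grid; the map's
#' marginal over m/z equals the peak-derived TIC trace. Gives a quick
#' overview of the sampled mass range and gradient shape.
#'
#' @param scans a [scan_table()] with MS1 peaks loaded.
#' @param rt_bin_s retention-time bin width (s), default 60.
#' @param mz_bin_th m/z bin width (Th), default 10.
#' @return list with `rt_edges`, `mz_edges` and `intensity` matrix
#'   (RT bins x m/z bins).
#' @export
tic_map <- function(scans, rt_bin_s = 60, mz_bin_th = 10) {
  if (is.null(scans$peaks)) stop("MS1 peaks must be loaded to build a TIC map")
  s <- scans$scans
  ms1 <- which(s$ms_level == 1L)
  rt_edges <- seq(0, max(c(s$rt_seconds, 0)) + rt_bin_s, by = rt_bin_s)
  rng <- scans$metadata$precursor_range
  mz_edges <- seq(rng[1], rng[2] + mz_bin_th, by = mz_bin_th)
  M <- matrix(0, length(rt_edges) - 1L, length(mz_edges) - 1L)
  for (i in ms1) {
    p <- scans$peaks[[i]]
    if (is.null(p) || nrow(p) == 0L) next
    rb <- findInterval(s$rt_seconds[i], rt_edges, rightmost.closed = FALSE)
    mb <- findInterval(p$mz, mz_edges, rightmost.closed = FALSE)
    ok <- mb >= 1L & mb <= ncol(M)
    for (b in unique(mb[ok])) M[rb, b] <- M[rb, b] + sum(p$intensity[mb == b & ok])
  }
  list(rt_edges = rt_edges, mz_edges = mz_edges, intensity = M)
}

#' Intensity-weighted mean m/z across the gradient
#'
#' The red m/z trace of the ion map: per retention-time bin, the mean MS1
#' centroid m/z weighted by intensity. `NA` for bins without signal.
#'
#' @param scans a [scan_table()] with MS1 peaks loaded.
#' @param rt_bin_s retention-time bin width (s), default 60.
#' @return data.frame with `rt_bin_lower`, `rt_bin_upper`, `mean_mz`.
#' @export
mean_mz_trace <- function(scans, rt_bin_s = 60) {
  if (is.null(scans$peaks)) stop("MS1 peaks must be loaded for the m/z trace")
  s <- scans$scans
  rt_edges <- seq(0, max(c(s$rt_seconds, 0)) + rt_bin_s, by = rt_bin_s)
  wsum <- numeric(length(rt_edges) - 1L)
  isum <- numeric(length(rt_edges) - 1L)
  for (i in which(s$ms_level == 1L)) {
    p <- scans$peaks[[i]]
    if (is.null(p) || nrow(p) == 0L) next
    rb <- findInterval(s$rt_seconds[i], rt_edges, rightmost.closed = FALSE)
    wsum[rb] <- wsum[rb] + sum(p$mz * p$intensity)
    isum[rb] <- isum[rb] + sum(p$intensity)
  }
  data.frame(rt_bin_lower = rt_edges[-length(rt_edges)],
             rt_bin_upper = rt_edges[-1],
             mean_mz = ifelse(isum > 0, wsum / isum, NA_real_))
}

#' Identifications across the gradient
#'
#' Counts identified precursors per retention-time bin per run.
#'
#' @param table a `precursor_table`.
#' @param rt_bin_s retention-time bin width (s), default 60.
#' @return data.frame with `run_id`, `rt_bin_lower`, `rt_bin_upper`, `n_ids`.
#' @export
ids_by_rt <- function(table, rt_bin_s = 60) {
  if (nrow(table) == 0L) {
    return(data.frame(run_id = character(), rt_bin_lower = numeric(),
                      rt_bin_upper = numeric(), n_ids = integer()))
  }
  edges <- seq(0, max(table$rt_seconds) + rt_bin_s, by = rt_bin_s)
  bin <- findInterval(table$rt_seconds, edges, rightmost.closed = FALSE)
  do.call(rbind, lapply(unique(table$run_id), function(r) {
    tb <- tabulate(bin[table$run_id == r], nbins = length(edges) - 1L)
    data.frame(run_id = r, rt_bin_lower = edges[-length(edges)],
               rt_bin_upper = edges[-1], n_ids = tb)
  }))
}

#' Precursor-wise signal-to-noise
#'
#' For each identified precursor, finds the MS1 scan nearest in retention
#' time, matches the centroid within a ppm tolerance of the precursor m/z and
#' reports intensity / noise. Missing when the precursor m/z is unknown, no
#' centroid matches, or the scan carries no noise estimates.
#'
#' @param table a `precursor_table` with `precursor_mz`.
#' @param scans a [scan_table()] with peaks (and noise values) loaded.
#' @param ppm_tol matching tolerance in ppm (default 10).
#' @return numeric vector of S/N values (NA where unavailable), one per record.
#' @export
precursor_sn <- function(table, scans, ppm_tol = 10) {
  if (is.null(scans$peaks)) stop("MS1 peaks must be loaded for S/N matching")
  s <- scans$scans
  ms1_idx <- which(s$ms_level == 1L)
  if (length(ms1_idx) == 0L) return(rep(NA_real_, nrow(table)))
  ms1_rt <- s$rt_seconds[ms1_idx]
  vapply(seq_len(nrow(table)), function(i) {
    mz <- table$precursor_mz[i]
    if (is.na(mz)) return(NA_real_)
    scan <- ms1_idx[which.min(abs(ms1_rt - table$rt_seconds[i]))]
    p <- scans$peaks[[scan]]
    if (is.null(p) || nrow(p) == 0L) return(NA_real_)
    tol <- mz * ppm_tol * 1e-6
    hit <- which(abs(p$mz - mz) <= tol)
    if (length(hit) == 0L) return(NA_real_)
    hit <- hit[which.max(p$intensity[hit])]
    if (!"noise" %in% names(p) || is.na(p$noise[hit]) || p$noise[hit] <= 0) {
      return(NA_real_)
    }
    p$intensity[hit] / p$noise[hit]
  }, numeric(1))
}
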