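#' Construct a ScanTable
#'
#' A ScanTable holds the per-scan acquisition record of one LC-MS run: one row
#' per spectrum with MS level, retention time, ion injection time, total ion
#' current (TIC) and, for MS2 scans, the isolation window. Centroid peak lists
#' can optionally be attached per scan. It is the substrate for all scan-level
#' quality-control metrics.
#'
#' @param scans data.frame with columns `scan_index`, `ms_level`, `rt_seconds`,
#'   `injection_time_ms`, `tic`, `isolation_center_mz`, `isolation_width_mz`.
#'   Missing values are `NA`; MS1 scans must have `NA` isolation fields.
#' @param metadata named list describing the run: `run_id`, `max_injection_ms`,
#'   `resolving_power`, `agc_target`, `precursor_range` (length-2 numeric, Th).
#' @param peaks optional list (same length as `nrow(scans)`) of data.frames
#'   with columns `mz`, `intensity` and optionally `noise`, each sorted by m/z.
#' @return an object of class `scan_table`.
#' @export
scan_table <- function(scans, metadata = run_metadata(), peaks = NULL) {
  required <- c("scan_index", "ms_level", "rt_seconds", "injection_time_ms",
                "tic", "isolation_center_mz", "isolation_width_mz")
  missing_cols <- setdiff(required, names(scans))
  if (length(missing_cols) > 0L) {
    stop("scan table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  scans <- as.data.frame(scans)[required]
  if (!is.null(peaks) && length(peaks) != nrow(scans)) {
    stop("`peaks` must have one element per scan")
  }
  x <- structure(list(metadata = metadata, scans = scans, peaks = peaks),
                 class = "scan_table")
  validate_scan_table(x)
  x
}

#' Run-level acquisition metadata
#'
#' @param run_id run identifier.
#' @param max_injection_ms configured maximum ion accumulation time (ms).
#' @param resolving_power Orbitrap resolving power setting.
#' @param agc_target automatic gain control target (charges).
#' @param precursor_range numeric length 2, scanned precursor m/z range (Th).
#' @return named list of class `run_metadata`.
#' @export
run_metadata <- function(run_id = "run", max_injection_ms = 300,
                         resolving_power = 70000L, agc_target = 3e6,
                         precursor_range = c(380, 1400)) {
  stopifnot(max_injection_ms > 0, resolving_power > 0,
            length(precursor_range) == 2, precursor_range[1] < precursor_range[2])
  structure(list(run_id = run_id, max_injection_ms = max_injection_ms,
                 resolving_power = as.integer(resolving_power),
                 agc_target = agc_target, precursor_range = precursor_range),
            class = "run_metadata")
}

validate_scan_table <- function(x) {
  s <- x$scans
  if (nrow(s) == 0L) return(invisible(x))
  if (any(!s$ms_level %in% c(1L, 2L))) {
    bad <- s$scan_index[!s$ms_level %in% c(1L, 2L)][1]
    stop("unsupported MS level in scan ", bad, " (only 1 and 2 are handled)")
  }
  if (any(diff(s$rt_seconds) < -1e-9)) {
    stop("retention times must be non-decreasing over the scan index")
  }
  if (any(s$ms_level == 1L & (!is.na(s$isolation_center_mz) | !is.na(s$isolation_width_mz)))) {
    stop("MS1 scans must not carry isolation window fields")
  }
  if (any(s$tic < 0, na.rm = TRUE)) stop("TIC must be non-negative")
  if (any(s$ms_level == 2L) && !any(s$ms_level == 1L)) {
    stop("a run with MS2 scans must contain at least one MS1 scan")
  }
  invisible(x)
}

#' @export
print.scan_table <- function(x, ...) {
  s <- x$scans
  cat(sprintf("ScanTable '%s': %d scans (%d MS1, %d MS2)%s\n",
              x$metadata$run_id, nrow(s), sum(s$ms_level == 1L),
              sum(s$ms_level == 2L),
              if (is.null(x$peaks)) ", no peaks" else ", peaks loaded"))
  if (nrow(s) > 0L) {
    cat(sprintf("  RT %.1f-%.1f s, total TIC %.3g\n",
                min(s$rt_seconds), max(s$rt_seconds), sum(s$tic, na.rm = TRUE)))
  }
  invisible(x)
}

#' Number of scans in a ScanTable
#' @param x a `scan_table`.
#' @return integer scan count.
#' @export
n_scans <- function(x) nrow(x$scans)

#' Write a ScanTable to TSV
#'
#' Scalar fields are written to `path` (UTF-8, '.' decimal separator, missing
#' values as empty fields, full numeric precision). If peaks are attached they
#' are written to a sidecar file `<path>.peaks.tsv` with one row per centroid.
#'
#' @param table a `scan_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(table, path) {
  s <- table$scans
  fmt <- function(v) ifelse(is.na(v), "", format(v, digits = 17, scientific = FALSE, trim = TRUE))
  out <- data.frame(scan_index = fmt(s$scan_index), ms_level = fmt(s$ms_level),
                    rt_seconds = fmt(s$rt_seconds),
                    injection_time_ms = fmt(s$injection_time_ms),
                    tic = fmt(s$tic),
                    isolation_center_mz = fmt(s$isolation_center_mz),
                    isolation_width_mz = fmt(s$isolation_width_mz))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  meta_path <- paste0(path, ".meta.tsv")
  md <- table$metadata
  utils::write.table(
    data.frame(key = c("run_id", "max_injection_ms", "resolving_power",
                       "agc_target", "range_lower_mz", "range_upper_mz"),
               value = c(md$run_id, fmt(md$max_injection_ms), fmt(md$resolving_power),
                         fmt(md$agc_target), fmt(md$precursor_range[1]),
                         fmt(md$precursor_range[2]))),
    meta_path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(table$peaks)) {
    pk <- do.call(rbind, lapply(seq_along(table$peaks), function(i) {
      p <- table$peaks[[i]]
      if (is.null(p) || nrow(p) == 0L) return(NULL)
      noise <- if ("noise" %in% names(p)) p$noise else rep(NA_real_, nrow(p))
      data.frame(scan_index = s$scan_index[i], mz = p$mz,
                 intensity = p$intensity, noise = noise)
    }))
    if (is.null(pk)) pk <- data.frame(scan_index = integer(), mz = numeric(),
                                      intensity = numeric(), noise = numeric())
    pk[] <- lapply(pk, function(v) ifelse(is.na(v), "", format(v, digits = 17, scientific = FALSE, trim = TRUE)))
    utils::write.table(pk, paste0(path, ".peaks.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a ScanTable from TSV
#'
#' Reads a table previously written by [write_scan_table()]; the round trip is
#' lossless for all scalar fields. A `<path>.peaks.tsv` sidecar, if present, is
#' read back into per-scan peak lists.
#'
#' @param path TSV path.
#' @return a `scan_table`.
#' @export
read_scan_table <- function(path) {
  s <- utils::read.delim(path, sep = "\t", na.strings = "", colClasses = "character")
  required <- c("scan_index", "ms_level", "rt_seconds", "injection_time_ms",
                "tic", "isolation_center_mz", "isolation_width_mz")
  missing_cols <- setdiff(required, names(s))
  if (length(missing_cols) > 0L) {
    stop("scan table file is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  scans <- data.frame(scan_index = as.integer(s$scan_index),
                      ms_level = as.integer(s$ms_level),
                      rt_seconds = as.numeric(s$rt_seconds),
                      injection_time_ms = as.numeric(s$injection_time_ms),
                      tic = as.numeric(s$tic),
                      isolation_center_mz = as.numeric(s$isolation_center_mz),
                      isolation_width_mz = as.numeric(s$isolation_width_mz))
  metadata <- run_metadata()
  meta_path <- paste0(path, ".meta.tsv")
  if (file.exists(meta_path)) {
    md <- utils::read.delim(meta_path, sep = "\t", colClasses = "character")
    kv <- stats::setNames(md$value, md$key)
    metadata <- run_metadata(run_id = kv[["run_id"]],
                             max_injection_ms = as.numeric(kv[["max_injection_ms"]]),
                             resolving_power = as.integer(kv[["resolving_power"]]),
                             agc_target = as.numeric(kv[["agc_target"]]),
                             precursor_range = as.numeric(c(kv[["range_lower_mz"]],
                                                            kv[["range_upper_mz"]])))
  }
  peaks <- NULL
  pk_path <- paste0(path, ".peaks.tsv")
  if (file.exists(pk_path)) {
    pk <- utils::read.delim(pk_path, sep = "\t", na.strings = "")
    peaks <- lapply(scans$scan_index, function(i) {
      sub <- pk[pk$scan_index == i, c("mz", "intensity", "noise"), drop = FALSE]
      rownames(sub) <- NULL
      sub
    })
  }
  scan_table(scans, metadata, peaks)
}
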