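#' Read per-scan acquisition metadata from an mzML file
#'
#' Extracts one record per spectrum, in file order: MS level, retention time
#' (seconds; the parser normalises the file's declared unit), ion injection
#' time (ms; `NA` where the file does not report it), TIC, and for MS2 scans
#' the isolation window reconstructed as center = target m/z and
#' width = lower offset + upper offset (missing when offsets are absent,
#' never defaulted). When `load_peaks = TRUE` the centroid peak lists are
#' attached; a TIC that the file does not declare (reported as 0 with a
#' non-empty spectrum) is then recomputed as the sum of peak intensities.
#'
#' Per-peak noise estimates are a vendor-specific extension that standard mzML
#' does not carry; peaks read from mzML therefore have `noise = NA` and
#' signal-to-noise metrics are reported as missing for such runs.
#'
#' @param path path to an mzML 1.1 file (indexed or plain), centroided spectra.
#' @param load_peaks logical; attach centroid peak lists (default `FALSE`).
#' @param metadata optional [run_metadata()]; defaults to `run_id` = file name.
#' @return a [scan_table()].
#' @export
read_mzml_scans <- function(path, load_peaks = FALSE, metadata = NULL) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) stop("failed to parse mzML file '", path,
                                              "': ", conditionMessage(e)))
  on.exit(mzR::close(handle))
  nspec <- length(handle)   # S4 method on the mzR handle
  if (is.null(metadata)) {
    metadata <- run_metadata(run_id = tools::file_path_sans_ext(basename(path)))
  }
  if (nspec == 0L) {
    empty <- data.frame(scan_index = integer(), ms_level = integer(),
                        rt_seconds = numeric(), injection_time_ms = numeric(),
                        tic = numeric(), isolation_center_mz = numeric(),
                        isolation_width_mz = numeric())
    return(scan_table(empty, metadata, peaks = if (load_peaks) list() else NULL))
  }
  h <- mzR::header(handle)
  if (any(!h$msLevel %in% c(1L, 2L))) {
    bad <- which(!h$msLevel %in% c(1L, 2L))[1]
    stop("unsupported MS level ", h$msLevel[bad], " in scan ", bad)
  }
  center <- ifelse(h$msLevel == 2L, h$isolationWindowTargetMZ, NA_real_)
  width <- ifelse(h$msLevel == 2L,
                  h$isolationWindowLowerOffset + h$isolationWindowUpperOffset,
                  NA_real_)
  it <- h$injectionTime
  it[!is.na(it) & it < 0] <- NA_real_
  scans <- data.frame(scan_index = seq_len(nspec), ms_level = h$msLevel,
                      rt_seconds = h$retentionTime, injection_time_ms = it,
                      tic = h$totIonCurrent, isolation_center_mz = center,
                      isolation_width_mz = width)
  peaks <- NULL
  if (load_peaks) {
    pklist <- mzR::peaks(handle)
    if (is.matrix(pklist)) pklist <- list(pklist)
    peaks <- lapply(pklist, function(m) {
      m <- m[order(m[, 1]), , drop = FALSE]
      data.frame(mz = m[, 1], intensity = m[, 2],
                 noise = rep(NA_real_, nrow(m)))
    })
    # recompute TIC from intensities where the file declares none
    derived <- vapply(peaks, function(p) sum(p$intensity), numeric(1))
    missing_tic <- (is.na(scans$tic) | scans$tic == 0) & derived > 0
    scans$tic[missing_tic] <- derived[missing_tic]
  }
  scan_table(scans, metadata, peaks)
}

#' Write a ScanTable to mzML
#'
#' Emits a valid centroided mzML 1.1 file carrying MS level, retention time,
#' ion injection time, TIC, isolation window and the peak lists, such that
#' [read_mzml_scans()] round-trips the scan schedule exactly. Scans without
#' attached peaks are written as empty spectra.
#'
#' @param scans a [scan_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(scans, path) {
  s <- scans$scans
  n <- nrow(s)
  if (n == 0L) {   # spectrum-free run: minimal valid mzML
    writeLines(c(
      '<?xml version="1.0" encoding="utf-8"?>',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
      '  <cvList count="1">',
      '    <cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo" version="4.1.0"/>',
      '  </cvList>',
      '  <fileDescription><fileContent>',
      '    <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
      '  </fileContent></fileDescription>',
      '  <softwareList count="1"><software id="sw" version="0"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>',
      '  <instrumentConfigurationList count="1"><instrumentConfiguration id="ic"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>',
      '  <dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>',
      sprintf('  <run id="%s" defaultInstrumentConfigurationRef="ic">', scans$metadata$run_id),
      '    <spectrumList count="0" defaultDataProcessingRef="dp"/>',
      '  </run>',
      '</mzML>'), path)
    return(invisible(path))
  }
  pk <- lapply(seq_len(n), function(i) {
    p <- if (!is.null(scans$peaks)) scans$peaks[[i]] else NULL
    if (is.null(p) || nrow(p) == 0L) {
      matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("mz", "intensity")))
    } else {
      cbind(mz = p$mz, intensity = p$intensity)
    }
  })
  npk <- vapply(pk, nrow, integer(1))
  bp_mz <- vapply(pk, function(m) if (nrow(m)) m[which.max(m[, 2]), 1] else 0, numeric(1))
  bp_int <- vapply(pk, function(m) if (nrow(m)) max(m[, 2]) else 0, numeric(1))
  low <- vapply(pk, function(m) if (nrow(m)) min(m[, 1]) else 0, numeric(1))
  high <- vapply(pk, function(m) if (nrow(m)) max(m[, 1]) else 0, numeric(1))
  ms2 <- s$ms_level == 2L
  hdr <- data.frame(
    seqNum = s$scan_index, acquisitionNum = s$scan_index, msLevel = s$ms_level,
    polarity = 1L, peaksCount = npk, totIonCurrent = s$tic,
    retentionTime = s$rt_seconds, basePeakMZ = bp_mz, basePeakIntensity = bp_int,
    collisionEnergy = ifelse(ms2, 27, 0), ionisationEnergy = 0,
    lowMZ = low, highMZ = high,
    precursorScanNum = 0L,
    precursorMZ = ifelse(ms2, s$isolation_center_mz, 0),
    precursorCharge = 0L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = ifelse(is.na(s$injection_time_ms), 0, s$injection_time_ms),
    filterString = NA_character_,
    spectrumId = paste0("scan=", s$scan_index),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(ms2, s$isolation_center_mz, NA_real_),
    isolationWindowLowerOffset = ifelse(ms2, s$isolation_width_mz / 2, NA_real_),
    isolationWindowUpperOffset = ifelse(ms2, s$isolation_width_mz / 2, NA_real_),
    scanWindowLowerLimit = scans$metadata$precursor_range[1],
    scanWindowUpperLimit = scans$metadata$precursor_range[2],
    stringsAsFactors = FALSE)
  mzR::writeMSData(pk, path, header = hdr, outformat = "mzml")
  invisible(path)
}
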