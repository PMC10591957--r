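#' Parse the plexDIA channel from a modified peptide sequence
#'
#' mTRAQ non-isobaric labels are encoded as bracketed modification tags in the
#' modified sequence. Both common dialects are recognised: `mTRAQ-K-0` /
#' `mTRAQ-nterm-4` style (delta after a site code) and `mTRAQ-d0` / `mTRAQd8`
#' style. The tag may occur anywhere in the sequence. A sequence carrying tags
#' of two different deltas is ambiguous and raises an error.
#'
#' @param modified_sequence character vector of modified sequences.
#' @return character vector with values `"d0"`, `"d4"`, `"d8"` or `"unlabeled"`.
#' @export
#' @examples
#' parse_channel("(mTRAQ-K-0)PEPTIDEK")  # "d0"
#' parse_channel("PEPTIDEK")             # "unlabeled"
parse_channel <- function(modified_sequence) {
  vapply(modified_sequence, function(seq) {
    hits <- regmatches(seq, gregexpr("mTRAQ[^)\\]]*?([048])", seq, perl = TRUE))[[1]]
    if (length(hits) == 0L) return("unlabeled")
    deltas <- unique(sub(".*([048])$", "\\1", hits))
    if (length(deltas) > 1L) {
      stop("ambiguous channel: sequence '", seq, "' carries mTRAQ tags with deltas ",
           paste(deltas, collapse = " and "))
    }
    paste0("d", deltas)
  }, character(1), USE.NAMES = FALSE)
}

strip_sequence <- function(modified_sequence) {
  out <- gsub("\\([^)]*\\)|\\[[^]]*\\]", "", modified_sequence)
  gsub("[^A-Z]", "", out)
}

# column alias map: canonical name -> accepted report headers (first hit wins)
.report_aliases <- list(
  run = c("Run", "File.Name"),
  modified_sequence = c("Modified.Sequence"),
  charge = c("Precursor.Charge", "Charge"),
  precursor_mz = c("Precursor.Mz"),
  protein_group = c("Protein.Group", "Protein.Ids"),
  rt = c("RT"),
  ms1_intensity = c("Ms1.Area", "Ms1.Translated"),
  ms2_intensity = c("Precursor.Quantity", "Precursor.Translated"),
  q_value = c("Q.Value"),
  channel_q = c("Channel.Q.Value"),
  translated_q = c("Translated.Q.Value")
)

#' Read a DIA-NN-style search report into a PrecursorTable
#'
#' Reads the tab-separated `report.tsv` dialect: one row per precursor per run
#' (per channel for plexDIA sets). Rows above the q-value threshold are
#' dropped, channels are parsed from the mTRAQ modification tags, retention
#' times are converted from minutes to seconds, and each record is flagged as
#' a translated identification when it exists only by cross-channel
#' propagation — i.e. its translated q-value passes the threshold while its
#' direct (channel) q-value does not.
#'
#' Duplicate (run, modified sequence, charge) rows keep the lowest-q row, with
#' a warning. Column-name dialects are resolved through a small alias map
#' (e.g. `Ms1.Area` / `Ms1.Translated`); unknown extra columns are ignored.
#'
#' @param path report TSV path.
#' @param q_threshold identifications with gating q-value above this are
#'   removed (default 0.01).
#' @param gate which q-value column gates channel-level identifications:
#'   `"auto"` uses `Channel.Q.Value` when present, else `Q.Value`.
#' @return a `precursor_table`: data.frame of precursor records with attribute
#'   `runs` (ordered distinct run ids).
#' @export
read_report <- function(path, q_threshold = 0.01, gate = c("auto", "q_value", "channel_q")) {
  gate <- match.arg(gate)
  raw <- utils::read.delim(path, sep = "\t", check.names = TRUE,
                           stringsAsFactors = FALSE)
  pick <- function(key, required = TRUE) {
    hit <- intersect(.report_aliases[[key]], names(raw))
    if (length(hit) == 0L) {
      if (required) stop("report is missing mandatory column: ",
                         .report_aliases[[key]][1])
      return(rep(NA, nrow(raw)))
    }
    raw[[hit[1]]]
  }
  num <- function(v, what) {
    if (is.character(v)) {
      v[v == ""] <- NA
      out <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(out))
      if (length(bad) > 0L) stop("non-numeric ", what, " at report row ", bad[1])
      out
    } else as.numeric(v)
  }
  tab <- data.frame(
    run_id = as.character(pick("run")),
    modified_sequence = as.character(pick("modified_sequence")),
    charge = as.integer(pick("charge")),
    precursor_mz = num(pick("precursor_mz", required = FALSE), "precursor m/z"),
    protein_group = as.character(pick("protein_group")),
    rt_seconds = num(pick("rt"), "RT") * 60,
    ms1_intensity = num(pick("ms1_intensity", required = FALSE), "MS1 intensity"),
    ms2_intensity = num(pick("ms2_intensity", required = FALSE), "MS2 intensity"),
    q_value = num(pick("q_value"), "q-value"),
    channel_q = num(pick("channel_q", required = FALSE), "channel q-value"),
    translated_q = num(pick("translated_q", required = FALSE), "translated q-value"),
    stringsAsFactors = FALSE)
  tab$ms1_intensity[!is.na(tab$ms1_intensity) & tab$ms1_intensity == 0] <- NA_real_
  tab$stripped_sequence <- strip_sequence(tab$modified_sequence)
  tab$channel <- parse_channel(tab$modified_sequence)
  direct_q <- if (gate == "q_value") tab$q_value else
    ifelse(is.na(tab$channel_q), tab$q_value, tab$channel_q)
  if (gate == "channel_q" && all(is.na(tab$channel_q))) {
    warning("gate = 'channel_q' requested but Channel.Q.Value absent; using Q.Value")
  }
  tab$translated <- !is.na(tab$translated_q) & tab$translated_q <= q_threshold &
    direct_q > q_threshold
  # gate: keep rows identified either directly or by translation
  keep <- direct_q <= q_threshold | tab$translated
  tab <- tab[keep, , drop = FALSE]
  precursor_table(tab)
}

#' Construct a PrecursorTable from precursor records
#'
#' @param records data.frame with (at least) the columns produced by
#'   [read_report()]. Duplicate (run, modified sequence, charge) keys are
#'   collapsed to the lowest-q row with a warning.
#' @return a `precursor_table` data.frame with attribute `runs`.
#' @export
precursor_table <- function(records) {
  records <- as.data.frame(records)
  needed <- c("run_id", "modified_sequence", "stripped_sequence", "charge",
              "protein_group", "rt_seconds", "ms1_intensity", "ms2_intensity",
              "q_value", "channel", "translated")
  for (col in setdiff(needed, names(records))) {
    records[[col]] <- if (col %in% c("translated")) logical(nrow(records)) else NA
  }
  if (!"precursor_mz" %in% names(records)) records$precursor_mz <- NA_real_
  bad_q <- !is.na(records$q_value) & (records$q_value < 0 | records$q_value > 1)
  if (any(bad_q)) stop("q-values must lie in [0, 1]")
  key <- paste(records$run_id, records$modified_sequence, records$charge, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate (run, precursor) rows collapsed to lowest q-value")
    records <- records[order(records$q_value), , drop = FALSE]
    records <- records[!duplicated(paste(records$run_id, records$modified_sequence,
                                         records$charge, sep = "\r")), , drop = FALSE]
    records <- records[order(records$run_id, records$modified_sequence, records$charge), ,
                       drop = FALSE]
  }
  rownames(records) <- NULL
  structure(records, class = c("precursor_table", "data.frame"),
            runs = unique(records$run_id))
}

#' @export
print.precursor_table <- function(x, ...) {
  cat(sprintf("PrecursorTable: %d records, %d run(s), channels: %s\n",
              nrow(x), length(attr(x, "runs")),
              paste(sort(unique(x$channel)), collapse = ", ")))
  NextMethod()
}

#' Write a normalized PrecursorTable to TSV
#'
#' @param table a `precursor_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_precursor_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
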