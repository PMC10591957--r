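#' Compute the full QC metric bundle and write a static report
#'
#' Runs every scan-level and report-level metric on a run, writes one tidy
#' TSV per metric plus PNG figures into `out_dir`, and assembles a single
#' self-contained HTML report (figures embedded as base64). Metric TSVs are
#' written deterministically: rerunning on the same inputs reproduces them
#' byte for byte.
#'
#' @param scans a [scan_table()] (peaks loaded enables the ion-map, feature
#'   and S/N sections).
#' @param table a `precursor_table`.
#' @param out_dir output directory.
#' @param table_unfiltered optional unfiltered report (data.frame in the
#'   DIA-NN dialect or `precursor_table`) for the FDR curve.
#' @param rt_bin_s retention-time bin width (s), default 60.
#' @param mz_bin_th m/z bin width (Th), default 10.
#' @param min_peptides minimum peptides per protein for the CV metric.
#' @param make_plots write PNG figures and the HTML report (default TRUE).
#' @return invisibly, a named list of the computed metric tables.
#' @export
qc_report <- function(scans, table, out_dir, table_unfiltered = NULL,
                      rt_bin_s = 60, mz_bin_th = 10, min_peptides = 3L,
                      make_plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  has_peaks <- !is.null(scans$peaks)
  metrics <- list()

  metrics$intensity_by_channel <- intensity_distribution(table, by_channel = TRUE)
  n_groups <- function(v) length(unique(v))
  if (n_groups(table$channel) >= 2L) {
    metrics$ratio_by_channel <- {
      r <- ratio_distribution(table, by = "channel")
      data.frame(group = names(r$medians), median_log2_ratio = as.numeric(r$medians))
    }
    cm <- completeness_matrix(table, by = "channel")
    metrics$completeness <- data.frame(
      group_a = rep(rownames(cm), times = ncol(cm)),
      group_b = rep(colnames(cm), each = nrow(cm)),
      jaccard = as.vector(cm))
  }
  ic <- id_counts(table, by = "channel", split_translated = TRUE,
                  level = "precursor")
  metrics$id_counts_precursor <- ic$counts
  pc <- id_counts(table, by = "channel", split_translated = TRUE,
                  level = "protein")
  metrics$id_counts_protein <- pc$counts
  if (!is.null(pc$union)) {
    metrics$protein_overlap <- data.frame(intersection = pc$intersection,
                                          union = pc$union)
  }
  metrics$ms1_quant_fraction <- ms1_quant_fraction(table, by = "run")
  metrics$quant_variability <- quant_variability(table, min_peptides = min_peptides)
  metrics$ids_by_rt <- ids_by_rt(table, rt_bin_s = rt_bin_s)
  if (!is.null(table_unfiltered)) {
    tu <- if (inherits(table_unfiltered, "precursor_table")) table_unfiltered else {
      tmp <- tempfile(fileext = ".tsv")
      utils::write.table(table_unfiltered, tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      on.exit(unlink(tmp), add = TRUE)
      read_report(tmp, q_threshold = 1)
    }
    metrics$ids_vs_fdr <- ids_vs_fdr(tu)
  }
  metrics$ms1_accumulation <- ms1_accumulation(scans, rt_bin_s = rt_bin_s)
  metrics$accumulation_by_window <- accumulation_by_window(scans, rt_bin_s = rt_bin_s)
  if (has_peaks) {
    tm <- tic_map(scans, rt_bin_s = rt_bin_s, mz_bin_th = mz_bin_th)
    metrics$tic_map <- data.frame(
      rt_bin_lower = rep(tm$rt_edges[-length(tm$rt_edges)], times = ncol(tm$intensity)),
      mz_bin_lower = rep(tm$mz_edges[-length(tm$mz_edges)], each = nrow(tm$intensity)),
      intensity = as.vector(tm$intensity))
    metrics$mean_mz_trace <- mean_mz_trace(scans, rt_bin_s = rt_bin_s)
    feats <- detect_features(scans)
    fs <- feature_summary(feats, table)
    metrics$features <- feats
    metrics$features_by_rt <- fs$by_rt
    metrics$feature_elution_lengths <- data.frame(elution_length_s = fs$elution_lengths)
    sn <- precursor_sn(table, scans)
    metrics$precursor_sn <- data.frame(run_id = table$run_id,
                                       modified_sequence = table$modified_sequence,
                                       charge = table$charge, sn = sn)
  }

  for (nm in names(metrics)) {
    utils::write.table(metrics[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (make_plots) render_html_report(metrics, out_dir)
  invisible(metrics)
}

# one PNG per plottable metric; base graphics, deterministic
plot_metric <- function(name, m, path) {
  grDevices::png(path, width = 900, height = 560, res = 110)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(4.5, 4.5, 2.5, 1))
  on.exit(graphics::par(op), add = TRUE)
  switch(name,
    intensity_by_channel = {
      groups <- unique(m$group)
      cols <- grDevices::hcl.colors(max(3L, length(groups)), "Dark 3")
      graphics::plot(NA, xlim = range(c(m$bin_lower, m$bin_upper)),
                     ylim = c(0, max(m$count)), xlab = "log10 MS1 intensity",
                     ylab = "precursors", main = "Precursor intensity by channel")
      for (i in seq_along(groups)) {
        s <- m[m$group == groups[i], ]
        graphics::lines(s$bin_lower, s$count, type = "s", col = cols[i], lwd = 2)
      }
      graphics::legend("topright", legend = groups, col = cols[seq_along(groups)],
                       lwd = 2, bty = "n")
    },
    accumulation_by_window = {
      wins <- unique(m$window_index)
      cols <- grDevices::hcl.colors(max(3L, length(wins)), "Viridis")
      graphics::plot(NA, xlim = range(c(m$rt_bin_lower, m$rt_bin_upper)) / 60,
                     ylim = c(0, max(m$mean_injection_ms, na.rm = TRUE) * 1.05),
                     xlab = "retention time (min)", ylab = "mean MS2 injection (ms)",
                     main = "MS2 accumulation time per isolation window")
      for (i in seq_along(wins)) {
        s <- m[m$window_index == wins[i], ]
        graphics::lines(s$rt_bin_lower / 60, s$mean_injection_ms, col = cols[i], lwd = 2)
      }
      graphics::legend("bottomright", legend = paste0(round(m$isolation_center_mz[match(wins, m$window_index)]), " Th"),
                       col = cols[seq_along(wins)], lwd = 2, bty = "n", cex = 0.8)
    },
    ms1_accumulation = {
      graphics::plot(m$rt_bin_lower / 60, m$mean_injection_ms, type = "b", pch = 19,
                     xlab = "retention time (min)", ylab = "mean MS1 injection (ms)",
                     main = "MS1 accumulation time across the gradient")
    },
    ids_by_rt = {
      graphics::plot(m$rt_bin_lower / 60, m$n_ids, type = "h", lwd = 4,
                     xlab = "retention time (min)", ylab = "identifications",
                     main = "Identified precursors across the gradient")
    },
    ids_vs_fdr = {
      graphics::plot(m$threshold, m$n_ids, type = "b", log = "x", pch = 19,
                     xlab = "q-value threshold", ylab = "identifications",
                     main = "Identifications vs FDR threshold")
    },
    mean_mz_trace = {
      graphics::plot(m$rt_bin_lower / 60, m$mean_mz, type = "l", col = "red", lwd = 2,
                     xlab = "retention time (min)", ylab = "mean m/z (Th)",
                     main = "Intensity-weighted mean m/z")
    },
    feature_elution_lengths = {
      graphics::hist(m$elution_length_s, breaks = 30, col = "grey70",
                     xlab = "elution length at base (s)", main = "Feature elution lengths")
    },
    NULL)
  invisible(path)
}

render_html_report <- function(metrics, out_dir) {
  plottable <- intersect(names(metrics),
                         c("intensity_by_channel", "accumulation_by_window",
                           "ms1_accumulation", "ids_by_rt", "ids_vs_fdr",
                           "mean_mz_trace", "feature_elution_lengths"))
  sections <- character(0)
  for (nm in names(metrics)) {
    png_path <- file.path(out_dir, paste0(nm, ".png"))
    img <- ""
    if (nm %in% plottable && nrow(metrics[[nm]]) > 0L) {
      ok <- tryCatch({plot_metric(nm, metrics[[nm]], png_path); TRUE},
                     error = function(e) FALSE)
      if (ok && file.exists(png_path)) {
        b64 <- jsonlite::base64_enc(readBin(png_path, "raw",
                                            n = file.info(png_path)$size))
        img <- sprintf('<img src="data:image/png;base64,%s" width="760"/>',
                       gsub("\n", "", b64))
      }
    }
    m <- metrics[[nm]]
    preview <- utils::capture.output(print(utils::head(as.data.frame(m), 8)))
    sections <- c(sections, sprintf(
      "<h2>%s</h2>\n<p>table: <code>%s.tsv</code> (%d rows)</p>\n%s\n<pre>%s</pre>",
      gsub("_", " ", nm), nm, nrow(as.data.frame(m)), img,
      paste(preview, collapse = "\n")))
  }
  html <- sprintf(
    "<!DOCTYPE html><html><head><meta charset='utf-8'><title>diaqc report</title>\n<style>body{font-family:sans-serif;max-width:900px;margin:2em auto}pre{background:#f5f5f5;padding:0.6em;overflow-x:auto}</style></head>\n<body><h1>diaqc acquisition report</h1>\n%s</body></html>",
    paste(sections, collapse = "\n"))
  writeLines(html, file.path(out_dir, "report.html"))
  invisible(file.path(out_dir, "report.html"))
}

#' QC subcommand: report bundle from an mzML file and a search report
#'
#' @param mzml_path mzML file path.
#' @param report_path DIA-NN-style report TSV.
#' @param out_dir output directory.
#' @param q_threshold identification q-value threshold (default 0.01).
#' @param load_peaks read centroid peaks (enables ion map/features).
#' @param ... passed to [qc_report()].
#' @return invisibly, the metric list from [qc_report()].
#' @export
cmd_qc <- function(mzml_path, report_path, out_dir, q_threshold = 0.01,
                   load_peaks = TRUE, ...) {
  if (!file.exists(report_path)) stop("report TSV not found: ", report_path)
  scans <- read_mzml_scans(mzml_path, load_peaks = load_peaks)
  table <- read_report(report_path, q_threshold = q_threshold)
  unf <- read_report(report_path, q_threshold = 1)
  qc_report(scans, table, out_dir, table_unfiltered = unf, ...)
}

#' Windows subcommand: compute and write an isolation-window scheme
#'
#' @param strategy `"equal_mz"`, `"equal_tic"` or `"equal_precursor"`.
#' @param n number of windows.
#' @param range precursor m/z range (Th).
#' @param out_path output scheme TSV path.
#' @param mzml_path mzML with MS1 peaks (required for `equal_tic`).
#' @param report_path report TSV (required for `equal_precursor`).
#' @return the `window_scheme`, invisibly.
#' @export
cmd_windows <- function(strategy = c("equal_mz", "equal_tic", "equal_precursor"),
                        n = 8L, range = c(380, 1400), out_path = "scheme.tsv",
                        mzml_path = NULL, report_path = NULL) {
  strategy <- match.arg(strategy)
  scheme <- switch(strategy,
    equal_mz = equal_mz_windows(range, n),
    equal_tic = {
      if (is.null(mzml_path)) stop("equal_tic placement needs an mzML file")
      scans <- read_mzml_scans(mzml_path, load_peaks = TRUE)
      equal_tic_windows(mz_histogram(scans, range = range), range, n)
    },
    equal_precursor = {
      if (is.null(report_path)) stop("equal_precursor placement needs a report TSV")
      tab <- read_report(report_path, q_threshold = 0.01)
      if (all(is.na(tab$precursor_mz))) stop("report carries no precursor m/z column")
      equal_precursor_windows(tab$precursor_mz[!is.na(tab$precursor_mz)], range, n)
    })
  bad <- validate_scheme(scheme)
  if (length(bad) > 0L) stop("invalid scheme: ", paste(bad, collapse = "; "))
  write_scheme(scheme, out_path)
  invisible(scheme)
}

#' Simulate subcommand: write a synthetic acquisition bundle
#'
#' @param out_dir output directory.
#' @param seed RNG seed.
#' @param n_precursors number of precursors (default 500).
#' @param n_windows number of equal-width MS2 windows (default 8).
#' @param n_ms1 survey scans per duty cycle (default 1).
#' @param ... additional [sim_config()] arguments.
#' @return invisibly, the [simulate_run()] output.
#' @export
cmd_simulate <- function(out_dir, seed, n_precursors = 500L, n_windows = 8L,
                         n_ms1 = 1L, ...) {
  cfg <- sim_config(n_precursors = n_precursors, seed = seed, ...)
  cyc <- duty_cycle(equal_mz_windows(cfg$mz_range, n_windows), n_ms1 = n_ms1,
                    max_injection_ms = cfg$max_injection_ms)
  sim <- simulate_run(cfg, cyc)
  write_sim_bundle(sim, out_dir)
  msg <- sprintf("simulated %d precursors x %d channels: %d report rows, %d scans",
                 cfg$n_precursors, nrow(cfg$channels),
                 nrow(sim$report_unfiltered), n_scans(sim$scans))
  message(msg)
  invisible(sim)
}

#' Read a YAML run configuration
#'
#' Minimal versioned schema: top-level `schema_version` plus any of the
#' argument names of [cmd_qc()], [cmd_windows()] and [cmd_simulate()]. CLI
#' flags override file values.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version)) {
    warning("config has no schema_version field; assuming version 1")
  }
  cfg
}
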