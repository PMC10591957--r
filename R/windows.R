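#' Construct an MS2 isolation-window scheme
#'
#' A window scheme is an ordered, contiguous tiling of the precursor m/z range
#' by MS2 isolation windows. Windows follow the half-open convention
#' `[lower, upper)`: a precursor sitting exactly on a boundary belongs to the
#' upper window.
#'
#' @param lower_mz,upper_mz numeric vectors of window edges (Th).
#' @param range numeric length 2, the full precursor range the scheme tiles;
#'   defaults to `c(lower_mz[1], upper_mz[n])`.
#' @return a `window_scheme` data.frame with columns `window_index`,
#'   `lower_mz`, `upper_mz`, `width` and attribute `range`.
#' @export
window_scheme <- function(lower_mz, upper_mz, range = NULL) {
  stopifnot(length(lower_mz) == length(upper_mz), length(lower_mz) >= 1)
  if (is.null(range)) range <- c(lower_mz[1], upper_mz[length(upper_mz)])
  structure(data.frame(window_index = seq_along(lower_mz), lower_mz = lower_mz,
                       upper_mz = upper_mz, width = upper_mz - lower_mz),
            class = c("window_scheme", "data.frame"), range = range)
}

#' Validate a window scheme
#'
#' Checks the tiling invariants: contiguity (each window's upper edge equals
#' the next window's lower edge), first lower edge at the range start, last
#' upper edge at the range end, positive widths, and widths summing to the
#' range width within 1e-9 Th.
#'
#' @param scheme a `window_scheme`.
#' @return character vector of violations; empty when the scheme is valid.
#' @export
validate_scheme <- function(scheme) {
  v <- character(0)
  rng <- attr(scheme, "range")
  n <- nrow(scheme)
  if (any(scheme$width <= 0)) v <- c(v, "non-positive window width")
  if (n > 1L && any(abs(scheme$upper_mz[-n] - scheme$lower_mz[-1]) > 1e-9)) {
    v <- c(v, "windows are not contiguous")
  }
  if (abs(scheme$lower_mz[1] - rng[1]) > 1e-9) {
    v <- c(v, "first window does not start at the range lower edge")
  }
  if (abs(scheme$upper_mz[n] - rng[2]) > 1e-9) {
    v <- c(v, "last window does not end at the range upper edge")
  }
  if (abs(sum(scheme$width) - (rng[2] - rng[1])) > 1e-9) {
    v <- c(v, "widths do not sum to the range width")
  }
  v
}

#' Upper edge of a stacked width list
#'
#' Method tables state schemes as a start m/z and a list of widths; the upper
#' edge of the tiling is the start plus the summed widths.
#'
#' @param widths positive window widths (Th).
#' @param start lower edge of the first window (Th).
#' @return upper edge (Th).
#' @export
scheme_upper_edge <- function(widths, start) {
  stopifnot(all(widths > 0))
  start + sum(widths)
}

#' Build a scheme from a start m/z and widths
#'
#' @param widths positive window widths (Th).
#' @param start lower edge of the first window (Th).
#' @return a `window_scheme`.
#' @export
scheme_from_widths <- function(widths, start) {
  stopifnot(all(widths > 0))
  edges <- start + cumsum(c(0, widths))
  window_scheme(edges[-length(edges)], edges[-1])
}

#' Equal-width isolation windows
#'
#' Tiles the precursor range with `n` windows of identical m/z width.
#'
#' @param range numeric length 2, precursor m/z range (Th).
#' @param n number of windows (>= 1).
#' @return a `window_scheme`.
#' @export
#' @examples
#' equal_mz_windows(c(380, 1400), 8)  # eight windows of 127.5 Th
equal_mz_windows <- function(range, n) {
  if (length(n) != 1L || n < 1L || n != round(n)) stop("`n` must be a positive integer")
  edges <- seq(range[1], range[2], length.out = n + 1)
  window_scheme(edges[-(n + 1)], edges[-1], range = range)
}

#' Summed-intensity histogram of MS1 ion current over m/z
#'
#' Bins the MS1 centroid intensities of a run over m/z; this empirical
#' ion-current distribution drives equal-TIC window placement.
#'
#' @param scans a [scan_table()] with MS1 peaks loaded.
#' @param range m/z range (Th); defaults to the run's precursor range.
#' @param bin_width_mz histogram bin width (Th), default 2.
#' @return an `mz_histogram`: list with `bin_edges` and `bin_mass`.
#' @export
mz_histogram <- function(scans, range = NULL, bin_width_mz = 2) {
  if (is.null(scans$peaks)) stop("MS1 peaks must be loaded to build an m/z histogram")
  if (is.null(range)) range <- scans$metadata$precursor_range
  edges <- seq(range[1], range[2], by = bin_width_mz)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  mass <- numeric(length(edges) - 1L)
  ms1 <- which(scans$scans$ms_level == 1L)
  for (i in ms1) {
    p <- scans$peaks[[i]]
    if (is.null(p) || nrow(p) == 0L) next
    inside <- p$mz >= range[1] & p$mz < range[2]
    if (!any(inside)) next
    bin <- findInterval(p$mz[inside], edges, rightmost.closed = FALSE)
    mass <- mass + vapply(seq_along(mass), function(b) sum(p$intensity[inside][bin == b]),
                          numeric(1))
  }
  structure(list(bin_edges = edges, bin_mass = mass), class = "mz_histogram")
}

#' Equal-ion-current isolation windows
#'
#' Places the window boundaries at the k/n quantiles (k = 1..n-1) of the
#' cumulative binned ion current, linearly interpolated within bins, so each
#' window receives approximately the same total ion current. Converges to the
#' exact equal-TIC tiling as the histogram bin width shrinks.
#'
#' @param hist an [mz_histogram()] covering `range`.
#' @param range precursor m/z range (Th).
#' @param n number of windows.
#' @return a `window_scheme`.
#' @export
equal_tic_windows <- function(hist, range, n) {
  if (n < 1L) stop("`n` must be a positive integer")
  total <- sum(hist$bin_mass)
  if (total <= 0) stop("degenerate input: histogram carries no ion current")
  cum <- c(0, cumsum(hist$bin_mass))
  targets <- total * seq_len(n - 1L) / n
  inner <- if (n > 1L) {
    stats::approx(x = cum, y = hist$bin_edges, xout = targets,
                  ties = "ordered")$y
  } else numeric(0)
  edges <- c(range[1], inner, range[2])
  window_scheme(edges[-(n + 1)], edges[-1], range = range)
}

#' Equal-precursor-count isolation windows
#'
#' Places boundaries at the empirical k/n quantiles of the precursor m/z
#' values, each boundary at the midpoint between the two adjacent order
#' statistics, so per-window precursor counts differ by at most 1. When
#' duplicated m/z values straddle a cut, the cut shifts to the nearest
#' position that keeps counts within that bound.
#'
#' @param precursor_mzs precursor m/z values (Th).
#' @param range precursor m/z range (Th).
#' @param n number of windows.
#' @return a `window_scheme`.
#' @export
equal_precursor_windows <- function(precursor_mzs, range, n) {
  if (n < 1L) stop("`n` must be a positive integer")
  x <- sort(precursor_mzs[precursor_mzs >= range[1] & precursor_mzs < range[2]])
  m <- length(x)
  if (m < n) stop("fewer precursors (", m, ") than windows (", n, ") inside the range")
  cut_after <- integer(0)          # boundary k placed after order statistic i_k
  inner <- numeric(0)
  if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      i <- round(k * m / n)
      i <- max(1L, min(m - 1L, i))
      # shift off runs of duplicated values: a cut inside a tie is impossible
      j <- i
      while (j >= 1L && x[j] == x[j + 1L]) j <- j - 1L
      jj <- i
      while (jj <= m - 1L && x[jj] == x[jj + 1L]) jj <- jj + 1L
      i <- if (j >= 1L && (i - j) <= (jj - i)) j else jj
      if (i < 1L || i > m - 1L) i <- max(1L, min(m - 1L, i))
      cut_after <- c(cut_after, i)
      inner <- c(inner, (x[i] + x[i + 1L]) / 2)
    }
    if (any(diff(inner) <= 0)) stop("could not place distinct boundaries; too many tied m/z values")
  }
  edges <- c(range[1], inner, range[2])
  window_scheme(edges[-(n + 1)], edges[-1], range = range)
}

#' Assign m/z values to scheme windows
#'
#' Uses the half-open `[lower, upper)` convention; values outside the scheme
#' range get `NA`.
#'
#' @param scheme a `window_scheme`.
#' @param mz numeric m/z values (Th).
#' @return integer window indices.
#' @export
assign_window <- function(scheme, mz) {
  edges <- c(scheme$lower_mz, scheme$upper_mz[nrow(scheme)])
  idx <- findInterval(mz, edges, rightmost.closed = FALSE)
  idx[idx < 1L | idx > nrow(scheme)] <- NA_integer_
  idx
}

#' Round scheme boundaries for instrument export
#'
#' Optionally snaps interior boundaries to a grid (default 0.5 Th) and
#' re-validates the tiling; the outer range edges are kept exact.
#'
#' @param scheme a `window_scheme`.
#' @param grid_th rounding grid (Th), default 0.5.
#' @return a rounded, validated `window_scheme`.
#' @export
round_scheme <- function(scheme, grid_th = 0.5) {
  n <- nrow(scheme)
  edges <- c(scheme$lower_mz, scheme$upper_mz[n])
  if (n > 1L) {
    edges[2:n] <- round(edges[2:n] / grid_th) * grid_th
  }
  out <- window_scheme(edges[-(n + 1)], edges[-1], range = attr(scheme, "range"))
  bad <- validate_scheme(out)
  if (length(bad) > 0L) stop("rounding broke the scheme: ", paste(bad, collapse = "; "))
  out
}

#' Write a scheme TSV and its method-table text
#'
#' Writes the scheme as TSV (`window_index`, `lower_mz`, `upper_mz`, `width`)
#' and, alongside it, a human-readable method-table line of the form
#' `"starting at 380 mz: 127.5Th, 127.5Th, ..."`.
#'
#' @param scheme a `window_scheme`.
#' @param path output TSV path; the text block goes to `<path>.txt`.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  utils::write.table(as.data.frame(scheme), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  txt <- sprintf("starting at %s mz: %s width",
                 format(scheme$lower_mz[1], trim = TRUE),
                 paste0(format(scheme$width, trim = TRUE), "Th", collapse = ", "))
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
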