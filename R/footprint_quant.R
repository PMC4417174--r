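# Capillary footprint quantitation. DMS methylates guanine N7 through the
# major groove; piperidine scission then yields one electropherogram peak per
# reactive guanine. Protein protection suppresses core-guanine peaks in the
# bound sample. Peaks are indexed to base positions by an index map, numerically
# integrated, and normalized to a distal control peak to cancel recovery
# differences between samples. DNase I traces are handled identically; there,
# enhanced cleavage (hypersensitivity) in the 5'-TTCC-3' strand is diagnostic
# of a site-specific ETS/DNA complex.

#' Assemble a capillary electropherogram
#'
#' @param scan Scan-point coordinates, strictly increasing.
#' @param signal Fluorescence intensities (non-negative after baseline
#'   subtraction; raw traces may carry a slow drift, see
#'   [subtract_baseline()]).
#' @param channel Dye label.
#' @param sample `"unbound"` or `"bound:<protein>"`.
#' @return An object of class `epherogram`.
#' @export
electropherogram <- function(scan, signal, channel = "FAM", sample = "unbound") {
  if (length(scan) != length(signal)) {
    stop_validation("scan and signal must have equal length")
  }
  if (any(diff(scan) <= 0)) stop_validation("scan must be strictly increasing")
  structure(list(scan = scan, signal = signal, channel = channel, sample = sample),
            class = "epherogram")
}

#' Rolling-minimum baseline subtraction
#'
#' Estimates slow baseline drift as the rolling minimum of the signal over a
#' window (in scan points) and subtracts it, clipping at zero. Capillary
#' traces drift slowly relative to peak widths, so a window much wider than a
#' peak leaves peak areas essentially untouched.
#'
#' @param trace An [electropherogram()].
#' @param window Window width in scan points (odd; default 201).
#' @return A baseline-subtracted `epherogram`.
#' @export
subtract_baseline <- function(trace, window = 201L) {
  n <- length(trace$signal)
  half <- floor(window / 2)
  base <- vapply(seq_len(n), function(i) {
    min(trace$signal[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  trace$signal <- pmax(trace$signal - base, 0)
  trace
}

#' Integrate indexed peaks of an electropherogram
#'
#' Trapezoidal integration of the signal over each base's scan window. The
#' index map emulates sizing software output: one disjoint window per indexed
#' base, with exactly one base flagged as the distal control peak.
#'
#' @param trace An [electropherogram()] (baseline-subtracted).
#' @param index_map Data frame with columns `base_index`, `window_start`,
#'   `window_end`, `is_control` (logical).
#' @param baseline_window If not `NULL`, apply [subtract_baseline()] with this
#'   window first. Default `NULL`.
#' @return A data frame of class `peak_table` with columns `base_index`,
#'   `area`, `normalized_area` (NA until [normalize_to_control()]),
#'   `is_control`.
#' @export
integrate_peaks <- function(trace, index_map, baseline_window = NULL) {
  need <- c("base_index", "window_start", "window_end", "is_control")
  if (!all(need %in% names(index_map))) {
    stop_validation("index_map must have columns: ", paste(need, collapse = ", "))
  }
  im <- index_map[order(index_map$window_start), , drop = FALSE]
  if (any(im$window_end < im$window_start)) {
    stop_validation("window_end must be >= window_start")
  }
  if (nrow(im) > 1 && any(im$window_start[-1] < im$window_end[-nrow(im)])) {
    stop_validation("index-map windows overlap")
  }
  if (min(im$window_start) < min(trace$scan) || max(im$window_end) > max(trace$scan)) {
    stop_validation("index-map windows extend beyond the trace")
  }
  if (!is.null(baseline_window)) trace <- subtract_baseline(trace, baseline_window)
  areas <- vapply(seq_len(nrow(im)), function(i) {
    idx <- trace$scan >= im$window_start[i] & trace$scan <= im$window_end[i]
    pracma::trapz(trace$scan[idx], trace$signal[idx])
  }, numeric(1))
  out <- data.frame(base_index = im$base_index, area = areas,
                    normalized_area = NA_real_,
                    is_control = as.logical(im$is_control))
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Normalize peak areas to the control peak
#'
#' Divides every area by the control-peak area (so the control normalizes to
#' exactly 1), cancelling sample-to-sample differences in recovery.
#'
#' @param table A `peak_table`.
#' @param control_index Base index of the control peak; defaults to the row
#'   flagged `is_control`.
#' @return The `peak_table` with `normalized_area` filled in.
#' @export
normalize_to_control <- function(table, control_index = NULL) {
  if (is.null(control_index)) {
    ctrl <- which(table$is_control)
  } else {
    ctrl <- which(table$base_index == control_index)
    table$is_control <- seq_len(nrow(table)) %in% ctrl
  }
  if (length(ctrl) != 1) {
    stop_validation("exactly one control peak is required, found ", length(ctrl))
  }
  if (table$area[ctrl] <= 0) stop_validation("control-peak area must be positive")
  table$normalized_area <- table$area / table$area[ctrl]
  table
}

check_normalized_pair <- function(bound, unbound) {
  if (any(is.na(bound$normalized_area)) || any(is.na(unbound$normalized_area))) {
    stop_validation("tables must be normalized first (see normalize_to_control)")
  }
  shared <- intersect(bound$base_index, unbound$base_index)
  if (length(shared) == 0) stop_validation("tables share no base indices")
  shared
}

#' Protection of the core guanines by a bound protein
#'
#' `protection_percent = 100 * (1 - sum(core bound) / sum(core unbound))`,
#' computed on control-normalized areas. Negative values indicate
#' hypersensitivity (more reactive when bound). Normalized core fractions are
#' reported at a granularity of 0.1.
#'
#' @param bound,unbound Normalized `peak_table`s sharing the core indices.
#' @param core_indices Base indices of the core guanines.
#' @param threshold Relative-change threshold forwarded to [flag_changes()]
#'   for the report's flag list. Default 0.20.
#' @return An object of class `protection_report` with
#'   `core_fraction_bound`, `core_fraction_unbound` (rounded to 0.1; raw
#'   values kept in `*_raw`), `protection_percent`, `delta_flags`.
#' @export
protection <- function(bound, unbound, core_indices, threshold = 0.20) {
  shared <- check_normalized_pair(bound, unbound)
  if (!all(core_indices %in% shared)) {
    stop_validation("core indices missing from one of the tables: ",
                    paste(setdiff(core_indices, shared), collapse = ", "))
  }
  cb <- sum(bound$normalized_area[bound$base_index %in% core_indices])
  cu <- sum(unbound$normalized_area[unbound$base_index %in% core_indices])
  if (cu <= 0) stop_validation("unbound core signal is zero; protection undefined")
  flags <- flag_changes(bound, unbound, threshold)
  structure(
    list(core_fraction_bound = round(cb, 1), core_fraction_unbound = round(cu, 1),
         core_fraction_bound_raw = cb, core_fraction_unbound_raw = cu,
         protection_percent = round(100 * (1 - cb / cu), 1),
         delta_flags = flags$base_index, precision = 0.1),
    class = "protection_report"
  )
}

#' @export
print.protection_report <- function(x, ...) {
  verdict <- if (x$protection_percent >= 0) "protection" else "hypersensitivity"
  cat(sprintf("<protection_report> core %0.1f (bound) vs %0.1f (unbound): %0.1f%% %s\n",
              x$core_fraction_bound, x$core_fraction_unbound,
              abs(x$protection_percent), verdict))
  if (length(x$delta_flags)) {
    cat("  >20% change at bases:", paste(x$delta_flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flag peaks whose areas change beyond a threshold
#'
#' Flags base i when `|bound(i) - unbound(i)| / unbound(i) > threshold` on
#' normalized areas (strict inequality); the control peak is excluded. A base
#' with zero unbound but nonzero bound signal is flagged with an infinite
#' relative change.
#'
#' @param bound,unbound Normalized `peak_table`s.
#' @param threshold Relative change threshold. Default 0.20 (the >20% rule).
#' @return Data frame with columns `base_index`, `relative_change`.
#' @export
flag_changes <- function(bound, unbound, threshold = 0.20) {
  shared <- check_normalized_pair(bound, unbound)
  b <- bound[match(shared, bound$base_index), ]
  u <- unbound[match(shared, unbound$base_index), ]
  keep <- !(b$is_control | u$is_control)
  bn <- b$normalized_area[keep]; un <- u$normalized_area[keep]
  rel <- ifelse(un > 0, abs(bn - un) / un, ifelse(bn > 0, Inf, 0))
  hit <- rel > threshold
  data.frame(base_index = shared[keep][hit], relative_change = rel[hit])
}

#' DNase I hypersensitivity check for site-specific binding
#'
#' A site-specific ETS/DNA complex widens the minor groove at the core and
#' enhances DNase I cleavage in the 5'-TTCC-3' strand. The verdict is
#' `site-specific` when any base in the interrogation window shows a
#' bound/unbound normalized ratio strictly greater than `factor`.
#'
#' @param bound,unbound Normalized DNase-channel `peak_table`s.
#' @param window Base indices to interrogate (non-empty).
#' @param factor Enhancement factor threshold. Default 2.
#' @return List with `site_specific` (logical), `max_ratio`, `hypersensitive_bases`.
#' @export
hypersensitivity_check <- function(bound, unbound, window, factor = 2) {
  if (length(window) == 0) stop_validation("interrogation window is empty")
  shared <- check_normalized_pair(bound, unbound)
  if (!all(window %in% shared)) {
    stop_validation("window bases missing from the tables: ",
                    paste(setdiff(window, shared), collapse = ", "))
  }
  bn <- bound$normalized_area[match(window, bound$base_index)]
  un <- unbound$normalized_area[match(window, unbound$base_index)]
  ratio <- ifelse(un > 0, bn / un, ifelse(bn > 0, Inf, 1))
  hit <- ratio > factor
  list(site_specific = any(hit), max_ratio = max(ratio),
       hypersensitive_bases = window[hit])
}

#' Read / write electropherogram CSVs and index maps
#'
#' Trace CSV columns: `scan`, `signal`. Index-map TSV columns: `base_index`,
#' `window_start`, `window_end`, `is_control`.
#'
#' @param path File path.
#' @param channel,sample Metadata for the trace reader.
#' @return An `epherogram` / index-map data frame.
#' @export
read_trace_csv <- function(path, channel = "FAM", sample = "unbound") {
  df <- utils::read.csv(path)
  if (!all(c("scan", "signal") %in% names(df))) {
    stop_validation("trace CSV must have columns scan, signal")
  }
  electropherogram(df$scan, df$signal, channel, sample)
}

#' @rdname read_trace_csv
#' @param trace An `epherogram` to write.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(scan = trace$scan, signal = trace$signal),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_trace_csv
#' @export
read_index_map <- function(path) {
  df <- utils::read.delim(path)
  df$is_control <- as.logical(df$is_control)
  df
}

#' @rdname read_trace_csv
#' @param index_map An index-map data frame to write.
#' @export
write_index_map <- function(index_map, path) {
  utils::write.table(index_map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
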