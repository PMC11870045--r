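#' Sweep-set container
#'
#' A `sweep_set` holds a family of time-aligned sweeps from one recording
#' protocol: equal-length sample vectors, the sampling rate, the channel
#' kind (`"voltage_mV"` or `"current_pA"`), the per-sweep injected step
#' amplitude and free-form annotations (cell id, condition, simulator
#' ground truth, ...).
#'
#' @param sample_rate sampling rate (Hz), > 0.
#' @param channel_kind `"voltage_mV"` or `"current_pA"`.
#' @param sweeps list of equal-length numeric sample vectors.
#' @param step_amplitudes per-sweep injected current (pA), same length as
#'   `sweeps`.
#' @param protocol optional [protocol_step_family()]-style protocol.
#' @param annotations free-form named list.
#' @return an object of class `sweep_set`.
#' @export
sweep_set <- function(sample_rate, channel_kind, sweeps, step_amplitudes,
                      protocol = NULL, annotations = list()) {
  if (!is.list(sweeps) || length(sweeps) == 0L)
    ephys_error("sweeps must be a non-empty list of numeric vectors",
                "format_error")
  lens <- vapply(sweeps, length, integer(1))
  if (length(unique(lens)) != 1L)
    ephys_error("all sweeps must have equal length", "format_error")
  if (length(step_amplitudes) != length(sweeps))
    ephys_error("one step amplitude per sweep required", "format_error")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    ephys_error("sample_rate must be > 0", "format_error")
  if (!channel_kind %in% c("voltage_mV", "current_pA"))
    ephys_error("channel_kind must be voltage_mV or current_pA",
                "format_error")
  structure(list(sample_rate = sample_rate, channel_kind = channel_kind,
                 sweeps = sweeps, step_amplitudes = step_amplitudes,
                 protocol = protocol, annotations = annotations),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps x %d samples @ %g Hz (%s)\n",
              length(x$sweeps), length(x$sweeps[[1]]), x$sample_rate,
              x$channel_kind))
  if (!is.null(x$annotations$condition))
    cat("  condition:", x$annotations$condition, "\n")
  cat("  step amplitudes (pA):",
      paste(utils::head(x$step_amplitudes, 8), collapse = ", "),
      if (length(x$step_amplitudes) > 8) "..." else "", "\n")
  invisible(x)
}

#' Read and write sweep sets in the plain-text TSV dialect
#'
#' The on-disk format is a diff-able TSV: '#'-prefixed `key=value` header
#' lines (`sample_rate_hz`, `channel_kind`, `step_amplitudes_pA` as a
#' comma-separated list, plus any scalar annotations as `annot:<key>`),
#' then a column header `time_s sweep_000 sweep_001 ...`, then one row per
#' sample. The time column is seconds from sweep start; samples are written
#' with 6 significant digits, so a file read back and rewritten reproduces
#' itself byte-for-byte.
#'
#' @param path file path.
#' @return `read_sweeps()` returns a [sweep_set()]; `write_sweeps()`
#'   invisibly returns `path`.
#' @export
read_sweeps <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) == 0L || !identical(hdr_idx, seq_along(hdr_idx)))
    ephys_error("header ('#' lines) must open the file", "format_error")
  hdr <- sub("^#\\s*", "", lines[hdr_idx])
  kv <- strsplit(hdr, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  need <- c("sample_rate_hz", "channel_kind", "step_amplitudes_pA")
  for (k in need)
    if (!k %in% keys)
      ephys_error(sprintf("header lacks key '%s' (lines 1-%d)",
                          k, length(hdr_idx)), "format_error")
  sample_rate <- as.numeric(vals[match("sample_rate_hz", keys)])
  channel_kind <- vals[match("channel_kind", keys)]
  amps <- as.numeric(strsplit(vals[match("step_amplitudes_pA", keys)],
                              ",", fixed = TRUE)[[1]])
  ann_keys <- grep("^annot:", keys)
  annotations <- as.list(vals[ann_keys])
  names(annotations) <- sub("^annot:", "", keys[ann_keys])
  body <- lines[-hdr_idx]
  if (length(body) < 2L)
    ephys_error("no sample rows found", "format_error")
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (cols[1] != "time_s")
    ephys_error(sprintf("column header (line %d) must start with time_s",
                        length(hdr_idx) + 1L), "format_error")
  n_sweeps <- length(cols) - 1L
  if (n_sweeps != length(amps))
    ephys_error("step_amplitudes_pA length does not match sweep columns",
                "format_error")
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  nf <- vapply(rows, length, integer(1))
  bad <- which(nf != length(cols))
  if (length(bad))
    ephys_error(sprintf("ragged row at line %d (%d fields, expected %d)",
                        length(hdr_idx) + 1L + bad[1], nf[bad[1]],
                        length(cols)), "format_error")
  m <- matrix(as.numeric(unlist(rows)), ncol = length(cols), byrow = TRUE)
  if (anyNA(m))
    ephys_error("non-numeric sample value in body", "format_error")
  sweep_set(sample_rate = sample_rate, channel_kind = channel_kind,
            sweeps = lapply(seq_len(n_sweeps), function(j) m[, j + 1L]),
            step_amplitudes = amps, annotations = annotations)
}

#' @rdname read_sweeps
#' @param x a [sweep_set()]. Only atomic scalar annotations are written;
#'   complex annotations (e.g. simulator ground truth) stay in memory.
#' @export
write_sweeps <- function(x, path) {
  stopifnot(inherits(x, "sweep_set"))
  hdr <- c(sprintf("# sample_rate_hz=%.10g", x$sample_rate),
           sprintf("# channel_kind=%s", x$channel_kind),
           sprintf("# step_amplitudes_pA=%s",
                   paste(sprintf("%.10g", x$step_amplitudes),
                         collapse = ",")))
  for (k in names(x$annotations)) {
    v <- x$annotations[[k]]
    if (is.atomic(v) && length(v) == 1L)
      hdr <- c(hdr, sprintf("# annot:%s=%s", k, as.character(v)))
  }
  n <- length(x$sweeps[[1]])
  tm <- sprintf("%.6f", (seq_len(n) - 1L) / x$sample_rate)
  cols <- vapply(x$sweeps, function(s) sprintf("%.6g", s),
                 character(n))
  body <- do.call(paste, c(list(tm), asplit(cols, 2), sep = "\t"))
  colhdr <- paste(c("time_s",
                    sprintf("sweep_%03d", seq_along(x$sweeps) - 1L)),
                  collapse = "\t")
  writeLines(c(hdr, colhdr, body), path)
  invisible(path)
}

#' Export the per-cell feature matrix
#'
#' Writes one row per cell with the 18 electrophysiological features in the
#' fixed documented order (see [feature_names()]), preceded by `cell_id`
#' and `condition` columns. Missing values are written as `NA`.
#'
#' @param features a data frame as returned by [extract_cell_features()]
#'   rows / [cohort_features()].
#' @param path output path; tab-separated.
#' @return invisibly, the data frame written.
#' @export
export_feature_matrix <- function(features, path) {
  cols <- c(intersect(c("cell_id", "condition"), names(features)),
            feature_names())
  miss <- setdiff(feature_names(), names(features))
  for (m in miss) features[[m]] <- NA
  out <- features[, cols, drop = FALSE]
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(out)
}

#' The 18 clustering features, in fixed column order
#'
#' rheobase (pA), membrane capacitance Cp (pF), resting potential V_m (mV),
#' input resistance R_in (MOhm), maximum spike frequency (Hz), sag
#' amplitude (mV), rebound spike (0/1), burst-or-adaptive firing category,
#' mean firing frequency (Hz), medium and fast AHP (mV), F-I midpoint (pA)
#' and steepness (Hz/pA), membrane time constant tau (ms), spike threshold
#' (mV), spike amplitude change (ratio), AP half-width (ms), mean
#' interevent interval (ms).
#'
#' @return character vector of length 18.
#' @export
feature_names <- function() {
  c("rheobase", "Cp", "V_m", "R_in", "max_freq", "sag_amp", "rebound",
    "burst_or_adaptive", "mean_freq", "mAHP", "fAHP", "midpoint",
    "steepness", "tau", "threshold", "amp_change", "half_width",
    "mean_ISI")
}

#' Adapters for binary acquisition formats
#'
#' Stubs behind the same read contract as [read_sweeps()]. Axon Binary
#' Format and NWB containers are binary; convert them to the TSV dialect
#' with an external exporter and read the result, or implement a full
#' adapter against these signatures.
#'
#' @param path file path.
#' @export
read_abf <- function(path) {
  ephys_error(paste0("ABF adapter not implemented: convert '", path,
                     "' to the TSV sweep dialect and use read_sweeps()"),
              "adapter_error")
}

#' @rdname read_abf
#' @export
read_nwb <- function(path) {
  ephys_error(paste0("NWB adapter not implemented: convert '", path,
                     "' to the TSV sweep dialect and use read_sweeps()"),
              "adapter_error")
}
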