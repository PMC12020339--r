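# Trace container and file formats.
#
# Internal unit convention: current in pA, conductance in nS, voltage in mV
# (so 1 nS x 1 mV = 1 pA), time in s, dwell in ms, areas in nm^2. Column
# names carry units to prevent silent drift.

#' Construct a current trace
#'
#' @param samples Numeric vector of current samples in pA.
#' @param sampling_rate Sampling rate in Hz.
#' @param voltage Applied potential in mV.
#' @param filter_cutoff Low-pass filter cutoff in Hz (NA if unfiltered).
#' @param metadata Named list of free-form key-value pairs.
#' @return Object of class \code{"nanopore_trace"}.
#' @export
nanopore_trace <- function(samples, sampling_rate, voltage = 100,
                           filter_cutoff = NA_real_, metadata = list()) {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop("trace needs at least 2 numeric samples", call. = FALSE)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive", call. = FALSE)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = as.numeric(sampling_rate),
                 voltage = as.numeric(voltage),
                 filter_cutoff = as.numeric(filter_cutoff),
                 metadata = metadata),
            class = "nanopore_trace")
}

#' @export
print.nanopore_trace <- function(x, ...) {
  cat(sprintf("Nanopore trace: %d samples @ %g kHz (%.3f s), %+g mV\n",
              length(x$samples), x$sampling_rate / 1000,
              length(x$samples) / x$sampling_rate, x$voltage))
  if (is.finite(x$filter_cutoff))
    cat(sprintf("  low-pass filtered at %g kHz\n", x$filter_cutoff / 1000))
  cat(sprintf("  current: mean %.1f pA, range [%.1f, %.1f] pA\n",
              mean(x$samples), min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
plot.nanopore_trace <- function(x, from = 0, to = NA, ...) {
  n <- length(x$samples)
  t <- seq(0, by = 1 / x$sampling_rate, length.out = n)
  keep <- t >= from & (is.na(to) | t <= to)
  graphics::plot(t[keep], x$samples[keep], type = "l",
                 xlab = "Time (s)", ylab = "Current (pA)", ...)
  invisible(x)
}

.trace_header_fields <- c("sampling_rate_Hz", "voltage_mV", "filter_cutoff_Hz")

#' Write a trace to file
#'
#' Text format: '#'-prefixed header lines (\code{# key: value}) followed by
#' two tab-separated columns \code{time_s}, \code{current_pA}. Binary
#' format (extension \code{.npb}): compact container with the same payload
#' (magic string, header block, little-endian doubles).
#'
#' @param trace A [nanopore_trace()].
#' @param path Output path; \code{format} defaults from the extension
#'   (\code{.npb} = binary, anything else = text).
#' @param format "text" or "binary".
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path,
                        format = if (grepl("\\.npb$", path)) "binary" else "text") {
  stopifnot(inherits(trace, "nanopore_trace"))
  format <- match.arg(format, c("text", "binary"))
  hdr <- c(sampling_rate_Hz = trace$sampling_rate,
           voltage_mV = trace$voltage,
           filter_cutoff_Hz = trace$filter_cutoff)
  meta <- trace$metadata
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(hdr))
      writeLines(sprintf("# %s: %.17g", k, hdr[[k]]), con)
    for (k in names(meta))
      writeLines(sprintf("# meta.%s: %s", k, as.character(meta[[k]])), con)
    writeLines("# columns: time_s\tcurrent_pA", con)
    t <- seq(0, by = 1 / trace$sampling_rate,
             length.out = length(trace$samples))
    writeLines(sprintf("%.9f\t%.17g", t, trace$samples), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar("NPTRACE1", con, eos = NULL)
    hdr_lines <- c(sprintf("%s=%.17g", names(hdr), hdr),
                   sprintf("meta.%s=%s", names(meta),
                           vapply(meta, as.character, "")))
    hdr_txt <- paste(hdr_lines, collapse = "\n")
    writeBin(nchar(hdr_txt, type = "bytes"), con, size = 4L, endian = "little")
    writeChar(hdr_txt, con, eos = NULL)
    writeBin(length(trace$samples), con, size = 4L, endian = "little")
    writeBin(trace$samples, con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a trace from file
#'
#' Accepts both formats written by [write_trace()]. For the text format the
#' time column must be uniform to within 1e-9 s and the
#' \code{sampling_rate_Hz} header is mandatory.
#'
#' @param path Input path.
#' @return A [nanopore_trace()].
#' @export
read_trace <- function(path) {
  magic <- readBin(path, "raw", n = 8L)
  if (length(magic) == 8L && rawToChar(magic) == "NPTRACE1")
    return(.read_trace_binary(path))
  .read_trace_text(path)
}

.parse_header <- function(keyvals) {
  meta <- list()
  hdr <- list()
  for (kv in keyvals) {
    key <- kv[[1]]; val <- kv[[2]]
    if (startsWith(key, "meta.")) {
      meta[[substring(key, 6L)]] <- val
    } else if (key != "columns") {
      num <- if (val %in% c("NA", "nan", "NaN")) NA_real_ else
        suppressWarnings(as.numeric(val))
      if (!val %in% c("NA", "nan", "NaN") && is.na(num))
        stop("malformed numeric header value for ", key, ": ", val,
             call. = FALSE)
      hdr[[key]] <- num
    }
  }
  if (is.null(hdr$sampling_rate_Hz))
    stop("trace header missing sampling_rate_Hz", call. = FALSE)
  list(hdr = hdr, meta = meta)
}

.read_trace_text <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  kv <- lapply(lines[is_hdr], function(l) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) != 3L) stop("malformed header line: ", l, call. = FALSE)
    list(trimws(m[2]), trimws(m[3]))
  })
  ph <- .parse_header(kv)
  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed data line at row ", which(lengths(parts) != 2L)[1L],
         call. = FALSE)
  t <- as.numeric(vapply(parts, `[[`, "", 1L))
  i <- as.numeric(vapply(parts, `[[`, "", 2L))
  dt <- diff(t)
  expect_dt <- 1 / ph$hdr$sampling_rate_Hz
  bad <- which(abs(dt - expect_dt) > 1e-9)
  if (length(bad))
    stop("non-uniform time column at sample index ", bad[1L] + 1L,
         " (gap ", signif(dt[bad[1L]], 6), " s)", call. = FALSE)
  nanopore_trace(i, ph$hdr$sampling_rate_Hz,
                 voltage = ph$hdr$voltage_mV %||% 100,
                 filter_cutoff = ph$hdr$filter_cutoff_Hz %||% NA_real_,
                 metadata = ph$meta)
}

.read_trace_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8L, useBytes = TRUE)
  hlen <- readBin(con, "integer", size = 4L, endian = "little")
  hdr_txt <- readChar(con, hlen, useBytes = TRUE)
  kv <- lapply(strsplit(hdr_txt, "\n")[[1L]], function(l) {
    p <- regmatches(l, regexec("^([^=]+)=(.*)$", l))[[1]]
    list(p[2], p[3])
  })
  ph <- .parse_header(kv)
  n <- readBin(con, "integer", size = 4L, endian = "little")
  samples <- readBin(con, "double", n = n, size = 8L, endian = "little")
  nanopore_trace(samples, ph$hdr$sampling_rate_Hz,
                 voltage = ph$hdr$voltage_mV %||% 100,
                 filter_cutoff = ph$hdr$filter_cutoff_Hz %||% NA_real_,
                 metadata = ph$meta)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

.event_columns <- c("event_id", "t_start_s", "dwell_ms", "i_mean_pA",
                    "g_block_nS", "a_ex_nm2", "state", "kicked_out", "label")

#' Write an event table as TSV
#'
#' Mandatory columns: event_id, t_start_s, dwell_ms, i_mean_pA, g_block_nS,
#' a_ex_nm2, state, kicked_out, label. Extra columns are preserved.
#'
#' @param events data.frame of events.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_events <- function(events, path) {
  missing_cols <- setdiff(.event_columns, names(events))
  if (length(missing_cols))
    stop("event table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an event table from TSV
#'
#' @param path Input path.
#' @return data.frame with the mandatory event columns (and any extras).
#' @export
read_events <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(.event_columns, names(tab))
  if (length(missing_cols))
    stop("event table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab$kicked_out <- as.logical(tab$kicked_out)
  tab
}

#' Assemble a standard event table
#'
#' Fills the mandatory columns from whatever is available, with NA for
#' quantities not yet computed (e.g. a_ex before classification).
#'
#' @param t_start_s,dwell_ms,i_mean_pA,g_block_nS Per-event numerics.
#' @param a_ex_nm2,state,kicked_out,label Optional classification columns.
#' @return data.frame in the standard column order.
#' @export
event_table <- function(t_start_s, dwell_ms, i_mean_pA, g_block_nS,
                        a_ex_nm2 = NA_real_, state = NA_character_,
                        kicked_out = NA, label = NA_character_) {
  n <- length(t_start_s)
  data.frame(event_id = seq_len(n), t_start_s = t_start_s,
             dwell_ms = dwell_ms, i_mean_pA = i_mean_pA,
             g_block_nS = g_block_nS,
             a_ex_nm2 = rep_len(a_ex_nm2, n),
             state = rep_len(state, n),
             kicked_out = rep_len(kicked_out, n),
             label = rep_len(label, n),
             stringsAsFactors = FALSE)
}
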