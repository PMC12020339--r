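# Resistive-pulse event detection.
#
# Threshold-crossing detection against a robust baseline: an event is a
# maximal run of samples below
#   open_level - max(threshold_sd * noise_sd, min_blockade_fraction * open_level)
# Runs separated by <= merge_gap samples are merged (flagged), runs shorter
# than min_dwell are discarded, and the blocked level is averaged over the
# run interior, excluding ceil(fs / (2 * fc)) samples at each edge to avoid
# filter rise/fall bias.

#' Robust baseline estimation
#'
#' Open level = mode of the running-median distribution (robust while
#' events occupy < 50% of any window); noise SD = scaled MAD of the
#' samples within +/- 3 SD of the open level.
#'
#' @param trace A [nanopore_trace()].
#' @param window Running-median window in samples (odd; >= 10 effective).
#' @return List with \code{open_level} (pA) and \code{noise_sd} (pA).
#' @export
estimate_baseline <- function(trace, window = 501L) {
  stopifnot(inherits(trace, "nanopore_trace"))
  window <- as.integer(window)
  if (window < 10L) stop("window must be at least 10 samples", call. = FALSE)
  if (window %% 2L == 0L) window <- window + 1L
  x <- trace$samples
  if (length(x) < window)
    stop("trace shorter than the baseline window", call. = FALSE)
  med <- stats::runmed(x, window)
  tab <- table(med)
  if (max(tab) > 0.25 * length(med)) {
    # discrete dominant level (noiseless / quantized traces): exact mode
    open <- as.numeric(names(tab)[which.max(tab)])
  } else {
    d <- stats::density(med, n = 512)
    open <- d$x[which.max(d$y)]
  }
  dev <- x - open
  sd0 <- stats::mad(dev, center = 0)
  if (sd0 == 0) return(list(open_level = open, noise_sd = 0))
  keep <- abs(dev) <= 3 * sd0
  list(open_level = open, noise_sd = stats::mad(dev[keep], center = 0))
}

#' Detect blockade events in a trace
#'
#' @param trace A [nanopore_trace()].
#' @param threshold_sd Detection threshold in baseline-noise SDs (default 5).
#' @param min_blockade_fraction Minimum blockade depth as a fraction of the
#'   open level (default 0.05); the effective threshold is the larger of
#'   the two criteria.
#' @param min_dwell Minimum event length in samples (default 3).
#' @param merge_gap Merge events separated by at most this many samples
#'   (default 2).
#' @param baseline_window Passed to [estimate_baseline()].
#' @param drop_truncated Exclude events touching the trace boundaries from
#'   the returned table (they are flagged either way). Default TRUE.
#' @return Event table (see [event_table()]) with extra columns
#'   \code{start_idx}, \code{end_idx} (0-based, half-open), \code{merged},
#'   \code{truncated}; attributes \code{open_level}, \code{noise_sd},
#'   \code{duration_s}.
#' @export
detect_events <- function(trace, threshold_sd = 5, min_blockade_fraction = 0.05,
                          min_dwell = 3L, merge_gap = 2L,
                          baseline_window = 501L, drop_truncated = TRUE) {
  stopifnot(inherits(trace, "nanopore_trace"))
  bl <- estimate_baseline(trace, baseline_window)
  x <- trace$samples
  n <- length(x)
  fs <- trace$sampling_rate
  depth <- max(threshold_sd * bl$noise_sd,
               min_blockade_fraction * abs(bl$open_level))
  if (depth <= 0)
    stop("degenerate trace: zero detection threshold", call. = FALSE)
  thr <- bl$open_level - depth

  below <- x < thr
  r <- rle(below)
  ends_all <- cumsum(r$lengths)
  starts_all <- ends_all - r$lengths + 1L
  ev_start <- starts_all[r$values]
  ev_end <- ends_all[r$values]

  empty <- function() {
    tab <- event_table(numeric(0), numeric(0), numeric(0), numeric(0))
    tab$start_idx <- integer(0); tab$end_idx <- integer(0)
    tab$merged <- logical(0); tab$truncated <- logical(0)
    structure(tab, open_level = bl$open_level, noise_sd = bl$noise_sd,
              duration_s = n / fs)
  }
  if (!length(ev_start)) return(empty())

  # merge runs separated by <= merge_gap samples
  merged_flag <- logical(length(ev_start))
  if (length(ev_start) > 1L) {
    gaps <- ev_start[-1L] - ev_end[-length(ev_end)] - 1L
    keep_s <- ev_start[c(TRUE, gaps > merge_gap)]
    grp <- cumsum(c(TRUE, gaps > merge_gap))
    keep_e <- tapply(ev_end, grp, max)
    merged_flag <- tapply(rep(1L, length(ev_start)), grp, length) > 1L
    ev_start <- keep_s
    ev_end <- as.integer(keep_e)
    merged_flag <- as.logical(merged_flag)
  }

  len <- ev_end - ev_start + 1L
  keep <- len >= min_dwell
  ev_start <- ev_start[keep]; ev_end <- ev_end[keep]
  merged_flag <- merged_flag[keep]; len <- len[keep]
  if (!length(ev_start)) return(empty())

  truncated <- ev_start == 1L | ev_end == n
  if (drop_truncated) {
    ev_start <- ev_start[!truncated]; ev_end <- ev_end[!truncated]
    merged_flag <- merged_flag[!truncated]; len <- len[!truncated]
    truncated <- rep(FALSE, length(ev_start))
  }
  if (!length(ev_start)) return(empty())

  # interior mean, excluding filter rise/fall samples at each edge
  n_edge <- if (is.finite(trace$filter_cutoff))
    as.integer(ceiling(fs / (2 * trace$filter_cutoff))) else 0L
  i_mean <- vapply(seq_along(ev_start), function(j) {
    s <- ev_start[j]; e <- ev_end[j]
    if (e - s + 1L > 2L * n_edge + 1L) { s <- s + n_edge; e <- e - n_edge }
    mean(x[s:e])
  }, 0)

  tab <- event_table(
    t_start_s = (ev_start - 1L) / fs,
    dwell_ms = len / fs * 1000,
    i_mean_pA = i_mean,
    g_block_nS = (bl$open_level - i_mean) / trace$voltage)
  tab$start_idx <- ev_start - 1L          # 0-based
  tab$end_idx <- ev_end                   # half-open
  tab$merged <- merged_flag
  tab$truncated <- truncated
  structure(tab, open_level = bl$open_level, noise_sd = bl$noise_sd,
            duration_s = n / fs)
}

#' Event frequency of a recording
#'
#' @param events Event table (or anything with \code{nrow}).
#' @param duration Recording duration in s.
#' @return Events per second.
#' @export
event_frequency <- function(events, duration) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  nrow(events) / duration
}

#' Significance stars for a p-value
#'
#' Mapping: p < 0.001 \code{***}; 0.001 < p < 0.01 \code{**};
#' 0.01 < p < 0.05 \code{*}; otherwise \code{n.s.}
#'
#' @param p p-value(s).
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "n.s.")))
}

#' Compare event frequencies between two groups of recordings
#'
#' Welch two-sided t-test on per-recording event frequencies.
#'
#' @param freq_a,freq_b Numeric vectors of per-recording frequencies
#'   (events/s), one entry per independent recording.
#' @return List with \code{p_value}, \code{stars}, \code{mean_a},
#'   \code{mean_b} and the underlying \code{htest}.
#' @export
compare_frequencies <- function(freq_a, freq_b) {
  if (length(freq_a) < 2L || length(freq_b) < 2L)
    stop("need at least 2 recordings per group", call. = FALSE)
  if (stats::sd(freq_a) == 0 && stats::sd(freq_b) == 0) {
    p <- if (isTRUE(all.equal(mean(freq_a), mean(freq_b)))) 1 else 0
    return(list(p_value = p, stars = significance_stars(p),
                mean_a = mean(freq_a), mean_b = mean(freq_b), htest = NULL))
  }
  ht <- stats::t.test(freq_a, freq_b)
  list(p_value = ht$p.value, stars = significance_stars(ht$p.value),
       mean_a = mean(freq_a), mean_b = mean(freq_b), htest = ht)
}
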