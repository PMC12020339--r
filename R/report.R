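# Peptide-discrimination report: the analysis endpoint.
#
# Collates per-analyte classified events into peak-conductance estimates,
# pairwise peak differences, state ratios, kick-out fractions and
# event-frequency comparisons with significance stars.

#' Discriminate peptides from classified event sets
#'
#' The package's top-level analysis. Takes one classified event table per
#' analyte and fits the discrimination summary: bootstrap peak blocking
#' conductance per analyte (kick-out events excluded), all pairwise peak
#' differences, orientation-state ratios, kick-out fractions, and — when
#' per-recording frequencies are supplied — pairwise Welch t-tests on
#' event frequency with significance stars and Holm-adjusted p-values.
#'
#' @param events_by_analyte Named list of classified event tables
#'   (see [classify_events()]), one per analyte.
#' @param frequencies_by_analyte Optional named list of per-recording
#'   event-frequency vectors (events/s) for significance testing.
#' @param duration_s Optional named vector of total recording durations,
#'   used to report an overall frequency per analyte.
#' @param n_boot,seed Bootstrap settings, see [bootstrap_peak()].
#' @return Object of class \code{"discrimination_report"}.
#' @export
discrimination_report <- function(events_by_analyte,
                                  frequencies_by_analyte = NULL,
                                  duration_s = NULL,
                                  n_boot = 1000L, seed = 1L) {
  labels <- names(events_by_analyte)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("events_by_analyte must be a named list", call. = FALSE)

  per <- lapply(labels, function(lb) {
    ev <- events_by_analyte[[lb]]
    keep <- ev[!isTRUE_vec(ev$kicked_out), , drop = FALSE]
    pk <- if (nrow(keep) >= 20L)
      bootstrap_peak(keep$g_block_nS, n_boot, seed) else NULL
    list(label = lb,
         n_events = nrow(ev),
         n_retained = nrow(keep),
         kickout_fraction = if (nrow(ev)) mean(isTRUE_vec(ev$kicked_out)) else NA_real_,
         state_i_fraction = if (nrow(keep) && any(keep$state %in% c("i", "ii")))
           mean(keep$state == "i") else NA_real_,
         peak = pk,
         frequency = if (!is.null(duration_s) && lb %in% names(duration_s))
           nrow(ev) / duration_s[[lb]] else NA_real_,
         scatter = data.frame(dwell_ms = keep$dwell_ms,
                              g_block_nS = keep$g_block_nS))
  })
  names(per) <- labels

  pairs <- if (length(labels) >= 2L) t(utils::combn(labels, 2L)) else
    matrix(character(0), 0, 2)
  npair <- nrow(pairs)
  peak_diff <- data.frame(
    analyte_a = pairs[, 1], analyte_b = pairs[, 2],
    peak_a_nS = rep(NA_real_, npair), peak_b_nS = rep(NA_real_, npair),
    diff_nS = rep(NA_real_, npair), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(peak_diff))) {
    pa <- per[[peak_diff$analyte_a[k]]]$peak
    pb <- per[[peak_diff$analyte_b[k]]]$peak
    if (!is.null(pa) && !is.null(pb)) {
      peak_diff$peak_a_nS[k] <- pa$peak
      peak_diff$peak_b_nS[k] <- pb$peak
      peak_diff$diff_nS[k] <- pa$peak - pb$peak
    }
  }

  freq_tests <- NULL
  if (!is.null(frequencies_by_analyte) && length(frequencies_by_analyte) >= 2L) {
    fl <- names(frequencies_by_analyte)
    fp <- t(utils::combn(fl, 2L))
    freq_tests <- data.frame(
      group_a = fp[, 1], group_b = fp[, 2],
      mean_a = NA_real_, mean_b = NA_real_, p_value = NA_real_,
      stringsAsFactors = FALSE)
    for (k in seq_len(nrow(freq_tests))) {
      cmp <- compare_frequencies(frequencies_by_analyte[[fp[k, 1]]],
                                 frequencies_by_analyte[[fp[k, 2]]])
      freq_tests$mean_a[k] <- cmp$mean_a
      freq_tests$mean_b[k] <- cmp$mean_b
      freq_tests$p_value[k] <- cmp$p_value
    }
    freq_tests$p_holm <- stats::p.adjust(freq_tests$p_value, "holm")
    freq_tests$stars <- significance_stars(freq_tests$p_value)
  }

  structure(list(analytes = per, peak_differences = peak_diff,
                 frequency_tests = freq_tests,
                 n_boot = n_boot, seed = seed, schema_version = "1.0"),
            class = "discrimination_report")
}

# vectorized isTRUE with NA -> FALSE
isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("Peptide discrimination report (%d analytes)\n",
              length(x$analytes)))
  for (a in x$analytes) {
    pk <- if (is.null(a$peak)) "   (too few events for a peak)"
      else sprintf("peak %.3f nS [%.3f, %.3f]",
                   a$peak$peak, a$peak$ci[1], a$peak$ci[2])
    cat(sprintf("  %-12s n=%4d (retained %4d, kick-out %4.1f%%)  %s\n",
                a$label, a$n_events, a$n_retained,
                100 * a$kickout_fraction, pk))
  }
  if (nrow(x$peak_differences)) {
    cat("Pairwise peak differences:\n")
    for (k in seq_len(nrow(x$peak_differences)))
      cat(sprintf("  %s - %s: %+.3f nS\n",
                  x$peak_differences$analyte_a[k],
                  x$peak_differences$analyte_b[k],
                  x$peak_differences$diff_nS[k]))
  }
  if (!is.null(x$frequency_tests)) {
    cat("Event-frequency comparisons (Welch t-test):\n")
    for (k in seq_len(nrow(x$frequency_tests)))
      cat(sprintf("  %s vs %s: %.2f vs %.2f events/s, p = %.3g (%s)\n",
                  x$frequency_tests$group_a[k], x$frequency_tests$group_b[k],
                  x$frequency_tests$mean_a[k], x$frequency_tests$mean_b[k],
                  x$frequency_tests$p_value[k], x$frequency_tests$stars[k]))
  }
  invisible(x)
}

#' @export
summary.discrimination_report <- function(object, ...) {
  tab <- data.frame(
    label = vapply(object$analytes, `[[`, "", "label"),
    n_events = vapply(object$analytes, `[[`, 0L, "n_events"),
    n_retained = vapply(object$analytes, `[[`, 0L, "n_retained"),
    kickout_fraction = vapply(object$analytes, `[[`, 0, "kickout_fraction"),
    state_i_fraction = vapply(object$analytes, function(a)
      a$state_i_fraction %||% NA_real_, 0),
    peak_nS = vapply(object$analytes, function(a)
      if (is.null(a$peak)) NA_real_ else a$peak$peak, 0),
    ci_lo_nS = vapply(object$analytes, function(a)
      if (is.null(a$peak)) NA_real_ else a$peak$ci[1], 0),
    ci_hi_nS = vapply(object$analytes, function(a)
      if (is.null(a$peak)) NA_real_ else a$peak$ci[2], 0),
    frequency_per_s = vapply(object$analytes, function(a)
      a$frequency %||% NA_real_, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  tab
}

#' @export
plot.discrimination_report <- function(x, ...) {
  cols <- grDevices::hcl.colors(max(3L, length(x$analytes)), "Dark 3")
  all_sc <- do.call(rbind, lapply(seq_along(x$analytes), function(i)
    cbind(x$analytes[[i]]$scatter, grp = i)))
  if (!nrow(all_sc)) stop("no retained events to plot", call. = FALSE)
  graphics::plot(all_sc$dwell_ms, all_sc$g_block_nS, log = "x",
                 col = cols[all_sc$grp], pch = 16, cex = 0.5,
                 xlab = "Dwell time (ms)", ylab = "Blocking conductance (nS)",
                 ...)
  graphics::legend("topright", legend = names(x$analytes),
                   col = cols[seq_along(x$analytes)], pch = 16, bty = "n")
  invisible(x)
}

#' Write a discrimination report to JSON (and optional TSV summary)
#'
#' @param report A [discrimination_report()].
#' @param path_json Output JSON path.
#' @param path_tsv Optional TSV path for the per-analyte summary table.
#' @return \code{path_json}, invisibly.
#' @export
write_report <- function(report, path_json, path_tsv = NULL) {
  per <- lapply(report$analytes, function(a) {
    list(label = a$label, n_events = a$n_events, n_retained = a$n_retained,
         kickout_fraction = a$kickout_fraction,
         state_i_fraction = a$state_i_fraction,
         peak_nS = if (is.null(a$peak)) NULL else a$peak$peak,
         ci_nS = if (is.null(a$peak)) NULL else a$peak$ci,
         frequency_per_s = a$frequency)
  })
  out <- list(schema_version = report$schema_version,
              n_boot = report$n_boot, seed = report$seed,
              analytes = per,
              peak_differences = report$peak_differences,
              frequency_tests = report$frequency_tests)
  jsonlite::write_json(out, path_json, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  if (!is.null(path_tsv))
    utils::write.table(summary(report), path_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path_json)
}
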