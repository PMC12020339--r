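# Synthetic single-channel trace generator.
#
# Emulates a nanopore recording: constant open-pore current at the applied
# voltage, Poisson-arriving blockade events per analyte class with two
# orientation states (vertical entry = smaller projected area, horizontal =
# larger), a separate gating-noise process, white Gaussian baseline noise
# injected before filtering, and a digital 4-pole low-pass Bessel filter.
# Full ground truth is returned for scoring detectors and classifiers.

#' Blocking conductance from projected area
#'
#' Inverse of the excluded-area relation: a molecule of projected area
#' \eqn{A} inside a pore of open area \eqn{S} and open conductance
#' \eqn{G_{open}} reduces the conductance by
#' \eqn{G_{block} = A \cdot G_{open} / S}.
#'
#' @param area Projected area in nm^2 (0 <= area <= pore_area).
#' @param open_conductance Open-pore conductance in nS.
#' @param pore_area Open-pore cross-sectional area in nm^2.
#' @return Blocking conductance in nS.
#' @export
blockade_from_area <- function(area, open_conductance, pore_area) {
  if (any(area < 0)) stop("area must be non-negative", call. = FALSE)
  if (any(area > pore_area))
    stop("area exceeds pore area: a molecule cannot block more than the pore",
         call. = FALSE)
  if (open_conductance <= 0 || pore_area <= 0)
    stop("open_conductance and pore_area must be positive", call. = FALSE)
  area * open_conductance / pore_area
}

#' Dwell-time distribution specification
#'
#' @param dist "lognormal" (default) or "exponential".
#' @param meanlog,sdlog Log-normal parameters (dwell in seconds).
#' @param rate Exponential rate in 1/s.
#' @param min Lower truncation bound in seconds (resampled if below).
#' @return List describing the distribution.
#' @export
dwell_spec <- function(dist = c("lognormal", "exponential"),
                       meanlog = log(1e-3), sdlog = 0.6, rate = 1000,
                       min = 2.5e-4) {
  dist <- match.arg(dist)
  list(dist = dist, meanlog = meanlog, sdlog = sdlog, rate = rate, min = min)
}

.draw_dwell <- function(spec, n) {
  draw <- function(m) switch(spec$dist,
    lognormal = stats::rlnorm(m, spec$meanlog, spec$sdlog),
    exponential = stats::rexp(m, spec$rate))
  d <- draw(n)
  for (i in 1:100) {
    bad <- d < spec$min
    if (!any(bad)) break
    d[bad] <- draw(sum(bad))
  }
  pmax(d, spec$min)
}

#' Analyte class specification for the simulator
#'
#' An analyte is modelled as a Bernoulli mixture over two orientation
#' states: vertical entry presents the smaller projected area, horizontal
#' the larger. Per event, the projected area is drawn from a Gaussian
#' around the state mean (truncated to the physical range) and converted to
#' a blocking conductance through [blockade_from_area()].
#'
#' @param label Class label.
#' @param rate Event rate in events/s.
#' @param area_vertical,area_horizontal State mean projected areas in nm^2.
#' @param area_sd Gaussian spread of the area within a state (nm^2).
#' @param p_vertical Orientation weight: probability of vertical entry.
#' @param dwell A [dwell_spec()].
#' @return List describing the class.
#' @export
analyte_class <- function(label, rate, area_vertical, area_horizontal,
                          area_sd = 0.15, p_vertical = 0.8,
                          dwell = dwell_spec()) {
  if (rate < 0) stop("rate must be non-negative", call. = FALSE)
  if (p_vertical < 0 || p_vertical > 1)
    stop("p_vertical must be in [0, 1]", call. = FALSE)
  list(label = label, rate = rate, area_vertical = area_vertical,
       area_horizontal = area_horizontal, area_sd = area_sd,
       p_vertical = p_vertical, dwell = dwell)
}

#' Gating-noise specification
#'
#' Spontaneous blockade-like excursions intrinsic to the pore, generated by
#' the same machinery as analyte events but labelled separately. Depths are
#' drawn uniformly in conductance (not via projected area).
#'
#' @param rate Events/s (default 0: no gating noise).
#' @param depth_range Blocking-conductance range in nS.
#' @param dwell A [dwell_spec()].
#' @return List describing the process.
#' @export
gating_noise_spec <- function(rate = 0, depth_range = c(0.2, 0.9),
                              dwell = dwell_spec("exponential", rate = 2500,
                                                 min = 1e-4)) {
  list(rate = rate, depth_range = depth_range, dwell = dwell)
}

#' Simulation configuration
#'
#' Defaults mirror the recording conditions emulated throughout the
#' package: +100 mV in 1 M KCl, 50 kHz sampling, 10 kHz 4-pole low-pass
#' Bessel filter, with the pore drawn from the 2.0--2.5 nm Hille-equivalent
#' diameter range.
#'
#' @param duration Trace duration in s.
#' @param pore A [pore_geometry()]; sets the open conductance and pore area.
#' @param voltage Applied potential in mV.
#' @param sampling_rate Sampling rate in Hz.
#' @param filter_cutoff Bessel filter cutoff in Hz; NA disables filtering.
#' @param baseline_noise_sd Gaussian baseline noise SD in pA (pre-filter).
#' @param analyte_classes List of [analyte_class()] entries.
#' @param gating_noise A [gating_noise_spec()].
#' @param seed Integer RNG seed.
#' @return Object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(duration,
                              pore = pore_geometry(2.2),
                              voltage = 100,
                              sampling_rate = 5e4,
                              filter_cutoff = 1e4,
                              baseline_noise_sd = 6,
                              analyte_classes = list(),
                              gating_noise = gating_noise_spec(),
                              seed = 1L) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (any(vapply(analyte_classes, `[[`, 0, "rate") < 0))
    stop("rates must be non-negative", call. = FALSE)
  structure(list(duration = duration, pore = pore, voltage = voltage,
                 sampling_rate = sampling_rate, filter_cutoff = filter_cutoff,
                 baseline_noise_sd = baseline_noise_sd,
                 analyte_classes = analyte_classes,
                 gating_noise = gating_noise, seed = as.integer(seed)),
            class = "simulation_config")
}

# 4-pole low-pass Bessel filter (bilinear transform), unity DC gain.
# Analog prototype poles are magnitude (-3 dB) normalized.
.bessel4_poles <- c(-1.37006783437475 + 0.410249717494158i,
                    -1.37006783437475 - 0.410249717494158i,
                    -0.995208764350013 + 1.25710573945224i,
                    -0.995208764350013 - 1.25710573945224i)

#' Apply a digital 4-pole low-pass Bessel filter
#'
#' Analog Bessel prototype (cutoff = -3 dB point) discretized by the
#' bilinear transform. The input is padded at both ends with its edge
#' values to suppress startup transients.
#'
#' @param x Numeric samples.
#' @param sampling_rate Hz.
#' @param cutoff -3 dB cutoff in Hz; must be below Nyquist.
#' @return Filtered samples, same length as \code{x}.
#' @export
bessel_lowpass <- function(x, sampling_rate, cutoff) {
  if (cutoff >= sampling_rate / 2)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  wc <- 2 * pi * cutoff
  p <- wc * .bessel4_poles
  k <- Re(prod(-p))
  zpg <- signal::bilinear(Sz = numeric(0), Sp = p, Sg = k, T = 1 / sampling_rate)
  ba <- signal::as.Arma(zpg)
  b <- Re(ba$b); a <- Re(ba$a)
  npad <- ceiling(5 * sampling_rate / cutoff)
  xp <- c(rep(x[1L], npad), x, rep(x[length(x)], npad))
  y <- signal::filter(b, a, xp)
  as.numeric(y[(npad + 1L):(npad + length(x))])
}

#' Simulate a nanopore recording
#'
#' Generates the ideal piecewise-constant current (open level
#' \eqn{G_{open} V}; during an event the level is reduced by
#' \eqn{G_{block} V}), adds white Gaussian noise, applies the Bessel
#' filter, and returns the trace together with the ground-truth event
#' table. Arrivals are Poisson per class; events are placed without overlap
#' by rejection sampling (at most 100 attempts per event). Identical seeds
#' give identical output.
#'
#' @param config A [simulation_config()].
#' @return List with elements \code{trace} (a [nanopore_trace()]) and
#'   \code{truth} (data.frame: label, state, t_start_s, t_end_s,
#'   g_block_nS, area_nm2).
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv())
  else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  g_open <- hille_conductance(config$pore)
  s_pore <- pore_area(config$pore$diameter)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)

  # draw event descriptors per class
  draw_class <- function(cl) {
    m <- stats::rpois(1L, cl$rate * config$duration)
    if (m == 0L) return(NULL)
    vertical <- stats::runif(m) < cl$p_vertical
    mu <- ifelse(vertical, cl$area_vertical, cl$area_horizontal)
    area <- stats::rnorm(m, mu, cl$area_sd)
    for (i in 1:100) {
      bad <- area <= 0 | area > s_pore
      if (!any(bad)) break
      area[bad] <- stats::rnorm(sum(bad), mu[bad], cl$area_sd)
    }
    area <- pmin(pmax(area, 1e-6), s_pore)
    data.frame(label = cl$label,
               state = ifelse(vertical, "vertical", "horizontal"),
               dwell = .draw_dwell(cl$dwell, m),
               g_block = blockade_from_area(area, g_open, s_pore),
               area = area, stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, lapply(config$analyte_classes, draw_class))
  gn <- config$gating_noise
  if (!is.null(gn) && gn$rate > 0) {
    m <- stats::rpois(1L, gn$rate * config$duration)
    if (m > 0L)
      ev <- rbind(ev, data.frame(
        label = "gating_noise", state = "n/a",
        dwell = .draw_dwell(gn$dwell, m),
        g_block = stats::runif(m, gn$depth_range[1], gn$depth_range[2]),
        area = NA_real_, stringsAsFactors = FALSE))
  }

  # non-overlapping placement by rejection, margin of one filter rise time
  margin <- if (is.finite(config$filter_cutoff)) 5 / config$filter_cutoff else 2 / fs
  starts <- numeric(0); ends <- numeric(0)
  if (!is.null(ev) && nrow(ev)) {
    if (sum(ev$dwell) > 0.8 * config$duration)
      stop("event density too high: requested events occupy > 80% of the trace",
           call. = FALSE)
    ord <- order(-ev$dwell)  # place long events first
    st <- numeric(nrow(ev))
    for (j in ord) {
      ok <- FALSE
      for (attempt in 1:100) {
        s0 <- stats::runif(1, margin, config$duration - ev$dwell[j] - margin)
        e0 <- s0 + ev$dwell[j]
        if (!any(s0 < ends + margin & e0 + margin > starts)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not place event without overlap after 100 attempts; ",
             "reduce rates or dwell times", call. = FALSE)
      starts <- c(starts, s0); ends <- c(ends, e0)
      st[j] <- s0
    }
    ev$t_start_s <- st
    ev$t_end_s <- st + ev$dwell
    ev <- ev[order(ev$t_start_s), , drop = FALSE]
  }

  # ideal current, then noise, then filter
  i_open <- g_open * config$voltage  # nS * mV = pA
  current <- rep(i_open, n)
  if (!is.null(ev) && nrow(ev)) {
    i1 <- pmax(1L, floor(ev$t_start_s * fs) + 1L)
    i2 <- pmin(n, ceiling(ev$t_end_s * fs))
    for (j in seq_len(nrow(ev)))
      current[i1[j]:i2[j]] <- i_open - ev$g_block[j] * config$voltage
  }
  if (config$baseline_noise_sd > 0)
    current <- current + stats::rnorm(n, 0, config$baseline_noise_sd)
  if (is.finite(config$filter_cutoff))
    current <- bessel_lowpass(current, fs, config$filter_cutoff)

  trace <- nanopore_trace(current, fs, config$voltage, config$filter_cutoff,
                          metadata = list(g_open_nS = g_open,
                                          pore_area_nm2 = s_pore,
                                          seed = config$seed))
  truth <- if (is.null(ev) || !nrow(ev)) {
    data.frame(label = character(0), state = character(0),
               t_start_s = numeric(0), t_end_s = numeric(0),
               g_block_nS = numeric(0), area_nm2 = numeric(0))
  } else {
    data.frame(label = ev$label, state = ev$state, t_start_s = ev$t_start_s,
               t_end_s = ev$t_end_s, g_block_nS = ev$g_block,
               area_nm2 = ev$area, stringsAsFactors = FALSE)
  }
  list(trace = trace, truth = truth)
}

#' Write simulator ground truth as TSV
#'
#' @param truth Ground-truth data.frame from [simulate_trace()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
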