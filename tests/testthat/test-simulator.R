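test_that("blockade_from_area is exact arithmetic and bounded", {
  expect_equal(blockade_from_area(3.8, 5.0, 3.8), 5.0, tolerance = 1e-15)
  expect_equal(blockade_from_area(0, 5.0, 3.8), 0)
  expect_equal(blockade_from_area(1.5, 5.0, 3.8), 1.5 * 5.0 / 3.8,
               tolerance = 1e-15)
  expect_error(blockade_from_area(4.0, 5.0, 3.8), "exceeds")
})

test_that("excluded-area relation and its inverse compose to identity", {
  set.seed(51)
  for (i in 1:200) {
    s <- runif(1, 1, 10)
    g_open <- runif(1, 1, 12)
    a <- runif(1, 0, s)
    expect_equal(projected_area_ex(blockade_from_area(a, g_open, s), g_open, s),
                 a, tolerance = 1e-12)
  }
})

test_that("event-free simulation gives the open level plus band-limited noise", {
  cfg <- simulation_config(duration = 0.5, pore = pore_geometry(2.2),
                           baseline_noise_sd = 5, seed = 3)
  sim <- simulate_trace(cfg)
  expect_equal(nrow(sim$truth), 0)
  i_open <- hille_conductance(cfg$pore) * cfg$voltage
  n <- length(sim$trace$samples)
  # filtered noise is correlated; use a conservative SE bound
  expect_lt(abs(mean(sim$trace$samples) - i_open), 3 * 5 / sqrt(n / 10))
  # the filter shrinks white noise: sd well below the injected 5 pA
  expect_lt(sd(sim$trace$samples), 5)
})

test_that("simulation is byte-identical for identical seeds", {
  su <- two_analyte_setup()
  cfg <- simulation_config(1, pore = su$pore, analyte_classes = su$classes,
                           gating_noise = gating_noise_spec(rate = 3),
                           seed = 99)
  a <- simulate_trace(cfg)
  b <- simulate_trace(cfg)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_trace(simulation_config(1, pore = su$pore,
                                         analyte_classes = su$classes,
                                         gating_noise = gating_noise_spec(rate = 3),
                                         seed = 100))
  expect_false(identical(a$trace$samples, c_$trace$samples))
})

test_that("ground truth partitions into classes and events never overlap", {
  su <- two_analyte_setup(rate = 8)
  cfg <- simulation_config(4, pore = su$pore, analyte_classes = su$classes,
                           gating_noise = gating_noise_spec(rate = 4),
                           seed = 5)
  tr <- simulate_trace(cfg)$truth
  expect_true(all(tr$label %in% c("R7W", "R7G", "gating_noise")))
  expect_true(all(tr$t_end_s > tr$t_start_s))
  expect_true(all(diff(tr$t_start_s) >= 0))
  expect_true(all(tr$t_start_s[-1] >= tr$t_end_s[-nrow(tr)]))
  # analytes carry areas, gating noise does not
  expect_true(all(is.na(tr$area_nm2[tr$label == "gating_noise"])))
  expect_true(all(!is.na(tr$area_nm2[tr$label != "gating_noise"])))
})

test_that("event counts follow the Poisson arrival model", {
  su <- two_analyte_setup(rate = 5)
  cfg <- simulation_config(60, pore = su$pore,
                           analyte_classes = su$classes["R7W"], seed = 8)
  n_ev <- nrow(simulate_trace(cfg)$truth)
  # Poisson(300) central 99% interval
  expect_gte(n_ev, qpois(0.005, 300))
  expect_lte(n_ev, qpois(0.995, 300))
})

test_that("full block with zero noise reaches 0 pA before filtering", {
  pore <- pore_geometry(2.0, 5, 10.5)
  s <- pore_area(2.0)
  cl <- analyte_class("full", rate = 5, area_vertical = s,
                      area_horizontal = s, area_sd = 0, p_vertical = 1,
                      dwell = dwell_spec(meanlog = log(2e-3), sdlog = 0))
  cfg <- simulation_config(2, pore = pore, baseline_noise_sd = 0,
                           filter_cutoff = NA, analyte_classes = list(cl),
                           seed = 12)
  sim <- simulate_trace(cfg)
  expect_gt(nrow(sim$truth), 0)
  expect_equal(min(sim$trace$samples), 0, tolerance = 1e-12)
  i_open <- hille_conductance(pore) * 100
  expect_true(all(sim$trace$samples %in% c(0, i_open)))
})

test_that("dwell times follow the configured distribution", {
  set.seed(61)
  d <- nanopept:::.draw_dwell(dwell_spec("exponential", rate = 1000, min = 0),
                              1000)
  expect_gt(ks.test(d, pexp, 1000)$p.value, 0.01)
  dl <- nanopept:::.draw_dwell(dwell_spec("lognormal", meanlog = log(1e-3),
                                          sdlog = 0.6, min = 0), 1000)
  expect_gt(ks.test(dl, plnorm, log(1e-3), 0.6)$p.value, 0.01)
  # truncation bound respected
  dm <- nanopept:::.draw_dwell(dwell_spec(min = 5e-4), 500)
  expect_gte(min(dm), 5e-4)
})

test_that("impossible event densities are rejected with a diagnostic", {
  pore <- pore_geometry(2.2)
  cl <- analyte_class("jam", rate = 2000,
                      area_vertical = 1.5, area_horizontal = 2,
                      dwell = dwell_spec(meanlog = log(5e-3), sdlog = 0))
  cfg <- simulation_config(0.5, pore = pore, analyte_classes = list(cl),
                           seed = 2)
  expect_error(simulate_trace(cfg), "density|overlap")
})

test_that("the Bessel filter is low-pass with unity DC gain", {
  fs <- 5e4; fc <- 1e4
  # DC gain
  x <- rep(7, 2000)
  expect_equal(mean(bessel_lowpass(x, fs, fc)[500:1500]), 7, tolerance = 1e-6)
  # attenuation at 2x cutoff exceeds attenuation at fc/10
  t <- seq(0, 0.05, by = 1 / fs)
  amp_of <- function(f) {
    y <- bessel_lowpass(sin(2 * pi * f * t), fs, fc)
    max(abs(y[500:2000]))
  }
  expect_gt(amp_of(1e3), 0.95)
  a_fc <- amp_of(fc)
  expect_gt(a_fc, 0.6); expect_lt(a_fc, 0.8)  # ~ -3 dB at cutoff
  expect_lt(amp_of(2e4), 0.35)
})

test_that("ground truth TSV export matches the truth table", {
  su <- two_analyte_setup()
  sim <- simulate_trace(simulation_config(1, pore = su$pore,
                                          analyte_classes = su$classes,
                                          seed = 4))
  f <- tempfile(fileext = ".tsv")
  write_ground_truth(sim$truth, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(sim$truth))
  expect_equal(back$g_block_nS, sim$truth$g_block_nS, tolerance = 1e-9)
})
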