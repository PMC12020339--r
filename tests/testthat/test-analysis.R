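test_that("excluded-area inference is the stated arithmetic", {
  expect_equal(projected_area_ex(5.0, 5.0, 3.8), 3.8)       # full block
  expect_equal(projected_area_ex(0, 5.0, 3.8), 0)
  expect_equal(projected_area_ex(1.68, 5.0, 3.8), 1.68 * 3.8 / 5.0,
               tolerance = 1e-15)
  expect_error(projected_area_ex(5.1, 5.0, 3.8), "over-block")
})

test_that("kick-out classification uses a strict less-than boundary", {
  expect_true(classify_kickout(1.19, 1.2))
  expect_false(classify_kickout(1.2, 1.2))   # boundary: not kicked out
  expect_false(classify_kickout(1.3, 1.2))
  expect_true(classify_kickout(0.59, 0.6))
  # kick-out fraction is monotone non-decreasing in the threshold
  set.seed(81)
  a <- runif(500, 0, 4)
  fr <- vapply(seq(0.2, 3, by = 0.2),
               function(th) mean(classify_kickout(a, th)), 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("orientation states split at the conductance threshold, ties to i", {
  expect_equal(classify_state(1.5), "i")
  expect_equal(classify_state(1.75), "i")    # inclusive boundary
  expect_equal(classify_state(1.76), "ii")
  set.seed(82)
  w <- 0.7
  g <- ifelse(runif(4000) < w, rnorm(4000, 1.4, 0.1), rnorm(4000, 2.3, 0.1))
  ratio <- mean(classify_state(g) == "i")
  expect_lt(abs(ratio - w), 0.03)
})

test_that("classify_events fills areas, kick-out and states per mode", {
  ev <- event_table(t_start_s = c(0.1, 0.2, 0.3),
                    dwell_ms = 1, i_mean_pA = 1,
                    g_block_nS = c(0.5, 1.6, 2.2))
  out <- classify_events(ev, g_open = 5.0, pore_area = 3.8, mode = "r7x",
                         label = "R7W")
  expect_equal(out$a_ex_nm2, c(0.5, 1.6, 2.2) * 3.8 / 5)
  expect_equal(out$kicked_out, c(TRUE, FALSE, FALSE))
  expect_equal(out$state, c("i", "i", "ii"))
  expect_equal(unique(out$label), "R7W")

  tf <- classify_events(ev, 5.0, 3.8, mode = "tf")
  expect_equal(tf$kicked_out, tf$a_ex_nm2 < 0.6)
  expect_equal(unique(tf$state), "unassigned")

  ev$g_block_nS[1] <- 6.0
  expect_warning(out2 <- classify_events(ev, 5.0, 3.8), "dropped")
  expect_equal(nrow(out2), 2)
})

test_that("area-distribution comparison applies the p > 0.10 consistency rule", {
  x <- c(1.5, 1.7, 1.9, 2.1, 2.3)
  cmp <- compare_area_distributions(x, x)
  expect_equal(cmp$p_value, 1.0)
  expect_true(cmp$consistent)

  set.seed(83)
  shifted <- compare_area_distributions(rnorm(100, 2, 0.2),
                                        rnorm(100, 3, 0.2))
  expect_lt(shifted$p_value, 0.001)
  expect_false(shifted$consistent)
  expect_error(compare_area_distributions(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("bootstrap peak recovers distribution modes deterministically", {
  # degenerate data: peak at the common value, zero-width CI
  allc <- rep(1.68, 30)
  pk <- bootstrap_peak(allc, n_boot = 200, seed = 1)
  expect_equal(pk$peak, 1.68)
  expect_equal(unname(diff(pk$ci)), 0)

  # unimodal Gaussian: the bootstrap peak estimates the sample's KDE mode,
  # which itself scatters around the population mean with SE ~ 0.025 at
  # n = 300, sd 0.08
  set.seed(84)
  g <- rnorm(300, 1.68, 0.08)
  pk <- bootstrap_peak(g, n_boot = 500, seed = 2)
  d <- density(g, bw = "nrd0", n = 512, from = min(g), to = max(g))
  sample_mode <- d$x[which.max(d$y)]
  expect_lt(abs(pk$peak - sample_mode), 0.01)
  expect_lt(abs(pk$peak - 1.68), 0.06)
  expect_true(pk$ci[1] <= pk$peak && pk$peak <= pk$ci[2])
  # averaged over draws the population mode is recovered tightly
  err <- vapply(1:10, function(i) {
    set.seed(400 + i)
    bootstrap_peak(rnorm(300, 1.68, 0.08), n_boot = 200, seed = i)$peak - 1.68
  }, 0)
  expect_lt(abs(mean(err)), 0.02)

  # determinism per seed
  expect_identical(bootstrap_peak(g, 300, seed = 9)$peak,
                   bootstrap_peak(g, 300, seed = 9)$peak)

  # bimodal mixture: the heavier mode wins
  set.seed(85)
  mix <- c(rnorm(260, 1.4, 0.06), rnorm(90, 2.3, 0.06))
  expect_lt(abs(bootstrap_peak(mix, 500, seed = 3)$peak - 1.4), 0.04)

  # scale equivariance
  pk1 <- bootstrap_peak(g, 300, seed = 5)$peak
  pk3 <- bootstrap_peak(g * 3, 300, seed = 5)$peak
  expect_equal(pk3, 3 * pk1, tolerance = 1e-9)

  expect_error(bootstrap_peak(rnorm(10), 200, 1), "at least 20")
  expect_error(bootstrap_peak(g, 50, 1), "at least 100")
})

test_that("discrimination report collates peaks, differences and frequencies", {
  set.seed(86)
  mk <- function(mu, n = 200) {
    ev <- event_table(t_start_s = runif(n, 0, 30), dwell_ms = rlnorm(n, 0, .5),
                      i_mean_pA = 1, g_block_nS = rnorm(n, mu, 0.08))
    classify_events(ev, g_open = 4.0, pore_area = 4.52, mode = "r7x")
  }
  rep2 <- discrimination_report(
    list(R7W = mk(1.68), R7G = mk(1.43)),
    frequencies_by_analyte = list(R7W = c(5.1, 4.9, 5.2, 5.4),
                                  R7G = c(5.0, 5.3, 4.8, 5.1)),
    duration_s = c(R7W = 30, R7G = 30),
    n_boot = 300, seed = 7)
  s <- summary(rep2)
  expect_equal(nrow(s), 2)
  expect_lt(abs(s$peak_nS[s$label == "R7W"] - 1.68), 0.05)
  expect_equal(nrow(rep2$peak_differences), 1)
  expect_lt(abs(rep2$peak_differences$diff_nS - 0.25), 0.08)
  expect_equal(nrow(rep2$frequency_tests), 1)
  expect_true(all(c("p_holm", "stars") %in% names(rep2$frequency_tests)))

  # single group: empty pairwise section
  rep1 <- discrimination_report(list(R7W = mk(1.68)), n_boot = 300, seed = 7)
  expect_equal(nrow(rep1$peak_differences), 0)

  # JSON export round trip of the headline numbers
  f <- tempfile(fileext = ".json")
  write_report(rep2, f, path_tsv = sub("json$", "tsv", f))
  js <- jsonlite::read_json(f)
  expect_equal(js$analytes$R7W$peak_nS, s$peak_nS[s$label == "R7W"])
  expect_equal(js$schema_version, "1.0")
  expect_true(file.exists(sub("json$", "tsv", f)))
})

test_that("identical-generator frequency comparisons are n.s. in >= 90% of seeds", {
  stars <- vapply(1:100, function(sd) {
    set.seed(sd)
    fa <- rpois(5, 50) / 10
    fb <- rpois(5, 50) / 10
    compare_frequencies(fa, fb)$stars
  }, "")
  expect_gte(mean(stars == "n.s."), 0.90)
})
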