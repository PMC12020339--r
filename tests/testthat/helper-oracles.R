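# Independent oracles used across the suite.

# Closed-form area of the union of two equal circles (radius r, center
# distance d): 2 pi r^2 minus the lens (intersection) area.
two_circle_union <- function(r, d) {
  if (d >= 2 * r) return(2 * pi * r^2)
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  2 * pi * r^2 - lens
}

# Term-by-term Henderson-Hasselbalch evaluation, written out explicitly
# and independently of the package's vectorized implementation.
hh_charge_oracle <- function(tokens, pH, pka) {
  q <- 0
  q <- q + 1 / (1 + 10^(pH - pka[["Nterm"]]))
  q <- q - 1 / (1 + 10^(pka[["Cterm"]] - pH))
  for (t in tokens) {
    if (t %in% c("K", "R", "H")) q <- q + 1 / (1 + 10^(pH - pka[[t]]))
    if (t %in% c("D", "E", "C", "Y")) q <- q - 1 / (1 + 10^(pka[[t]] - pH))
  }
  q
}

# Brute-force tryptic cleavage: scan every position and cut where the
# residue is K/R and the next is not P.
digest_oracle <- function(seq) {
  tok <- strsplit(seq, "")[[1]]
  frags <- character(0)
  cur <- ""
  for (i in seq_along(tok)) {
    cur <- paste0(cur, tok[i])
    if (tok[i] %in% c("K", "R") && i < length(tok) && tok[i + 1] != "P") {
      frags <- c(frags, cur)
      cur <- ""
    }
  }
  c(frags, cur)
}

# Interval-overlap matching of detected against true events; returns
# recall and precision. A pair matches when the intervals overlap.
score_detection <- function(detected, truth) {
  if (!nrow(truth)) return(list(recall = NA, precision = NA))
  d_s <- detected$t_start_s
  d_e <- detected$t_start_s + detected$dwell_ms / 1000
  hit_truth <- vapply(seq_len(nrow(truth)), function(i)
    any(d_s < truth$t_end_s[i] & d_e > truth$t_start_s[i]), TRUE)
  hit_det <- vapply(seq_along(d_s), function(j)
    any(truth$t_start_s < d_e[j] & truth$t_end_s > d_s[j]), TRUE)
  list(recall = mean(hit_truth),
       precision = if (length(d_s)) mean(hit_det) else NA)
}

# Simulation setup used by the discrimination tests: a 2.4 nm pore and two
# oligo-arginine-like analytes whose vertical-state blocking-conductance
# peaks are placed at 1.68 and 1.43 nS.
two_analyte_setup <- function(rate = 10, area_sd_nS = 0.08, p_vertical = 0.85) {
  pore <- pore_geometry(2.4, length = 10, conductivity = 10.5)
  g_open <- hille_conductance(pore)
  s <- pore_area(pore$diameter)
  to_area <- function(g) g * s / g_open
  list(pore = pore, g_open = g_open, pore_area = s,
       classes = list(
         R7W = analyte_class("R7W", rate,
                             area_vertical = to_area(1.68),
                             area_horizontal = to_area(1.68) + 1.0,
                             area_sd = to_area(area_sd_nS),
                             p_vertical = p_vertical),
         R7G = analyte_class("R7G", rate,
                             area_vertical = to_area(1.43),
                             area_horizontal = to_area(1.43) + 1.0,
                             area_sd = to_area(area_sd_nS),
                             p_vertical = p_vertical)))
}
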