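# nanopept

Single-molecule nanopore peptide sensing, from raw single-channel current
traces to peptide discrimination.

Biological nanopores read out single peptides as transient reductions of the
ionic current through the pore (resistive pulses). `nanopept` implements the
full analysis chain used in that kind of experiment, for people who analyze
— or want to prototype detectors for — single-channel recordings:

1. **Trace simulation** (`simulate_trace()`): open-pore current at +100 mV,
   Poisson-arriving blockade events with two orientation states, a separate
   gating-noise process, Gaussian baseline noise, and a digital 4-pole
   low-pass Bessel filter (10 kHz at 50 kHz sampling by default), with full
   ground truth for scoring.
2. **Event detection** (`detect_events()`): robust baseline from the mode of
   the running-median distribution, threshold-crossing event extraction,
   dwell time and blocking conductance per event.
3. **Pore sizing** (`hille_conductance()`, `hille_diameter()`): the Hille
   equation links open conductance *G*<sub>open</sub> to geometry,

   *G* = σ / ( 4*l* / (π *d*²) + 1/*d* ),

   a cylindrical channel in series with two orifice access resistances.
4. **Excluded-area inference** (`projected_area_ex()`): each event's
   blocking conductance *G*<sub>block</sub> converts to the projected area
   the molecule presented inside the pore,

   *A*<sub>ex</sub> = *G*<sub>block</sub> · *S* / *G*<sub>open</sub>,

   with *S* the open-pore cross-section. Events with *A*<sub>ex</sub> below
   a threshold are classified as **kicked out** (entered and retreated
   without translocating); the blocking-conductance split at 1.75 nS
   separates vertical from horizontal entry orientations.
5. **Geometric reference** (`build_peptide_structure()`,
   `area_distribution()`): projected areas of a molecular structure (PDB or
   idealized builder) as the union of van der Waals atom disks, evaluated
   over the full 30°-step Euler rotation grid (1728 rotations), for
   comparison with the measured *A*<sub>ex</sub> distribution
   (`compare_area_distributions()`, consistent when Welch p > 0.10).
6. **Discrimination** (`bootstrap_peak()`, `discrimination_report()`):
   per-analyte peak blocking conductance as the median of KDE modes over
   bootstrap resamples with percentile confidence intervals, pairwise peak
   differences, state ratios, kick-out fractions and event-frequency
   comparisons (Welch t-tests with significance stars and Holm adjustment).

Peptide chemistry utilities round this out: `average_mass()`,
`net_charge()` (Henderson–Hasselbalch with an EMBOSS-style pKa table,
alkylated cysteine supported as lowercase `c`), and `tryptic_digest()`
(cleave after K/R, not before P).

## Worked example

Two oligo-arginine analytes whose vertical-entry peaks are placed at 1.68
and 1.43 nS are simulated on a 2.4 nm pore, detected, classified and
discriminated:

```r
library(nanopept)
pore  <- pore_geometry(2.4, length = 10, conductivity = 10.5)
g_open <- hille_conductance(pore); s <- pore_area(2.4)
to_area <- function(g) g * s / g_open   # nS -> nm^2 on this pore
classes <- list(
  R7W = analyte_class("R7W", 10, to_area(1.68), to_area(1.68) + 1.0,
                      to_area(0.08), p_vertical = 0.85),
  R7G = analyte_class("R7G", 10, to_area(1.43), to_area(1.43) + 1.0,
                      to_area(0.08), p_vertical = 0.85))
run_one <- function(label, seed) {
  sim <- simulate_trace(simulation_config(30, pore = pore,
                                          analyte_classes = classes[label],
                                          seed = seed))
  ev <- detect_events(sim$trace)
  classify_events(ev, g_open, s, mode = "r7x", label = label)
}
report <- discrimination_report(list(R7W = run_one("R7W", 101),
                                     R7G = run_one("R7G", 102)),
                                n_boot = 1000, seed = 103)
print(report)
```

```
Peptide discrimination report (2 analytes)
  R7W          n= 294 (retained  294, kick-out  0.0%)  peak 1.677 nS [1.643, 1.710]
  R7G          n= 303 (retained  303, kick-out  0.0%)  peak 1.464 nS [1.408, 1.481]
Pairwise peak differences:
  R7W - R7G: +0.213 nS
```

Reading this: ~300 events per analyte were simulated, every one was
detected and none fell below the 1.2 nm² kick-out threshold; the bootstrap
peak conductances recover the configured 1.68/1.43 nS peaks to within the
bootstrap confidence intervals, and the peak separation (0.21 nS, target
0.25 nS) is what discriminates the two peptides.

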