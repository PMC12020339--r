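---
title: "Nanopore peptide discrimination: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanopore peptide discrimination: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanopept)
```

## The measurement model

A protein nanopore in a lipid bilayer under an applied potential $V$ passes
an open-state current $I_{open} = G_{open} V$. A peptide entering the pore
excludes electrolyte volume and transiently reduces the current; each such
blockade event is summarized by its dwell time and its *blocking
conductance*

$$G_{block} = \frac{I_{open} - I_{blocked}}{V},$$

the conductance *drop*, so that bulkier peptides give larger values. The
package's central inference converts $G_{block}$ into the projected
(excluded) area the molecule presented perpendicular to the pore axis:

$$A_{ex} = \frac{G_{block}\, S}{G_{open}},$$

where $S = \pi (d/2)^2$ is the open-pore cross-section. This assumes the
blocked pore behaves as the open pore minus the molecule's silhouette —
a purely geometric, ohmic picture that ignores surface charge, electroosmotic
coupling and entropic effects. Its virtue is that it is invertible and puts
measured events and molecular structures on the same axis (nm²).

Two classifications follow directly from $A_{ex}$ and $G_{block}$:

* **Kick-out.** An event whose $A_{ex}$ is below the smallest area the
  molecule can physically present is not a translocation; the molecule
  entered and retreated. The threshold is strict (`<`), with conventional
  values of 1.2 nm² for oligo-arginine analyses and 0.6 nm² for
  tryptic-fragment panels. Kicked-out events are excluded from
  discrimination statistics.
* **Orientation state.** Short linear peptides enter either vertically
  (small silhouette, state i) or horizontally (large silhouette, state ii);
  the conductance range is split at 1.75 nS, ties assigned to state i. The
  split is exposed as a parameter because it is strictly valid only for
  pores of the size it was calibrated on.

## Pore geometry: the Hille equation

Open conductance and pore diameter are linked by a cylinder-plus-access
model,

$$G = \frac{\sigma}{\dfrac{4 l}{\pi d^2} + \dfrac{1}{d}},$$

with $\sigma$ the solution conductivity (S/m, numerically nS/nm), $l$ the
channel length and $d$ the diameter, all in nm. `hille_diameter()` is the
exact positive-root inverse (round trip below $10^{-12}$ nm). Defaults are
$\sigma = 10.5$ S/m (1 M KCl near room temperature) and $l = 5$ nm; both
are recorded in every output because inferred diameters are meaningless
without them. Note an internal tension of the geometric model: on a
~2 nm pore with $l = 5$ nm, blocking conductances of 1.4–1.7 nS map to
excluded areas *below* the 1.2 nm² kick-out threshold, whereas $l = 10$ nm
places them comfortably above it. Analyses in this package that need a
concrete pore therefore use $d = 2.4$ nm, $l = 10$ nm — the choice is a
modelling decision, not a measured constant, and is printed alongside all
derived quantities.

## Geometric reference: projected areas on the Euler grid

The reference distribution $A_{MD}$ comes from rotating a 3D structure over
the full extrinsic $x \to y \to z$ Euler grid in 30° steps ($12^3 = 1728$
rotations, retained literally, without deduplicating equivalent rotations)
and measuring, at each rotation, the area of the union of the atoms' van
der Waals disks projected on the plane perpendicular to the pore axis.
Rasterization (pixel counting at 0.02 nm default resolution) was chosen
over Monte Carlo for determinism; halving the raster step changes areas by
under 1%, and single-sphere and two-disk cases agree with closed forms to
under 1%. Bondi radii are keyed by element; unknown elements fall back to
0.17 nm with a warning.

Structures come from PDB files or from `build_peptide_structure()`, an
idealized internal-coordinate builder: standard bond lengths and angles,
trans peptide bonds, fixed backbone dihedrals, heavy atoms only. The
default backbone is polyproline-II-like ($\phi = -75°$, $\psi = +145°$),
the consensus solution conformation of short arginine-rich peptides, with
side chains at their most common rotamer ($\chi_1$ gauche⁻, later angles
trans). For RRRRRRRG this yields a minimum grid projected area of
1.32 nm² — the quantity `scripts/acceptance.R` recomputes. Two limitations
are worth naming: a solution ensemble is replaced by one idealized
conformer, and omitting hydrogens shrinks the envelope slightly; both push
the minimum area a little low relative to an MD-refined, all-atom
reference.

## The synthetic trace generator

`simulate_trace()` emulates a single-channel recording chain:

1. Ideal piecewise-constant current: open level $G_{open} V$; during an
   event the level drops by $G_{block} V$. Events arrive as a Poisson
   process per analyte class and are placed without overlap by rejection
   (≤100 attempts per event; failure is a diagnostic error, since the
   analysis assumes single-file translocation).
2. Per event, the orientation is Bernoulli (vertical with probability
   `p_vertical`), the projected area Gaussian around the state mean
   (truncated to $(0, S]$), and $G_{block}$ follows by the area relation.
   Dwells are log-normal by default (exponential available), truncated
   below at 0.25 ms so events are well resolved at the default bandwidth.
3. Gating noise — spontaneous blockade-like excursions intrinsic to the
   pore — is generated by the same machinery but labelled separately, with
   depths drawn directly in conductance (uniform 0.2–0.9 nS) and fast
   exponential dwells. These distributions are free parameters of the
   generator, not measured quantities.
4. White Gaussian noise (default SD 6 pA) is added *before* filtering, so
   the measured baseline noise is band-limited as in a real recording, and
   the sum is passed through a digital 4-pole low-pass Bessel filter
   (bilinear transform of the magnitude-normalized analog prototype;
   10 kHz cutoff, 50 kHz sampling, +100 mV by default).

What the generator deliberately does not model: electroosmotic/
electrophoretic capture physics (arrival rates are set, not derived), 1/f
and dielectric noise, baseline drift, multi-level sub-states within an
event, and overlapping translocations. Passing tests on synthetic traces
therefore demonstrates correctness of the *analysis* under the stated
noise model, not robustness to every artifact of real recordings.

## Event detection

`estimate_baseline()` takes the open level as the mode of the
running-median distribution (window 501 samples), which is robust while
events occupy well under half of any window; when the running median has a
dominant exact value (noiseless or quantized traces) that value is used
exactly. Noise SD is the scaled MAD of samples within ±3 SD of the open
level. `detect_events()` thresholds at
$\max(k\,\hat\sigma,\; f\, I_{open})$ below the open level with $k = 5$
and $f = 0.05$ by default, discards runs shorter than 3 samples, merges
runs separated by ≤2 samples (flagged), flags and by default drops events
touching the trace edges, and estimates the blocked level from the run
interior, excluding $\lceil f_s / 2 f_c \rceil$ samples at each edge
because the Bessel filter smears edges over ~2–3 samples at 50 kHz/10 kHz.
None of these defaults is a reproduction of any published setting; they
are package choices, exposed as arguments. On noiseless rectangular pulses
detection is exact (boundaries and $G_{block}$ to floating point); on
filtered, noisy simulator output with ≥20% blockades and ≥0.2 ms dwells it
achieves ≥95% recall and precision against ground truth.

## Discrimination statistics

Peak blocking conductance per analyte is estimated by a bootstrap over
events: each resample (with replacement, same $n$, ≥20 events required)
contributes the mode of a kernel-density estimate (Silverman bandwidth,
512-point grid over the data range); the reported peak is the median of
resample modes, the CI their 2.5/97.5 percentiles, all deterministic per
seed. The median-of-modes tracks the *sample* mode very closely (within
~$10^{-4}$ nS in testing); the sample mode itself carries sampling error
of roughly 0.025 nS at $n = 300$, SD 0.08 nS, which bounds what any peak
estimator can promise from one recording. Measured-vs-geometric area
consistency uses a Welch two-sided t-test with the conventional
"consistent when $p > 0.10$" rule; event-frequency comparisons use Welch
t-tests over per-recording frequencies with the star convention
(\*: 0.01<p<0.05, \*\*: 0.001<p<0.01, \*\*\*: p<0.001) and Holm-adjusted
p-values alongside the raw ones.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 1728-rotation grids at
0.02 nm raster (~4 s for an 82-atom peptide), simulated recordings of
10–30 s at 50 kHz (0.5–1.5 M samples) with ~300 events per analyte, and
1000 bootstrap resamples. Boundary conventions are documented where they
bite: kick-out is strict `<`, the state split is inclusive `≤` (ties to
state i), event indices are 0-based half-open, dwell is reported in ms and
conductance in nS (1 nS × 1 mV = 1 pA). Degenerate inputs — empty
structures, zero-variance comparisons, traces shorter than the baseline
window, event densities that cannot be placed without overlap — are
rejected with diagnostics rather than silently handled.

## Known limitations

* The excluded-area relation is a geometric approximation; it cannot
  separate shape from charge effects on blockade depth.
* The Hille parameterization ($l$, $\sigma$) is an assumption; diameters
  and the kick-out interpretation shift with it (see above).
* The idealized conformer builder replaces a conformational ensemble with
  one structure; its minimum projected area is expected to sit somewhat
  below an all-atom, solution-refined value.
* Bootstrap peaks from a single recording inherit the sample-mode error;
  comparisons between analytes measured on *different* pores additionally
  inherit pore-size differences that the 1.75 nS split does not absorb.
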