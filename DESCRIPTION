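Package: nanopept
Title: Nanopore Peptide Sensing: Trace Simulation, Blockade Detection and
    Excluded-Area Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for single-channel nanopore peptide sensing.
    Simulates Bessel-filtered current-time traces with resistive-pulse
    blockade events and gating noise, detects blockades and extracts dwell
    times and blocking conductances, links open-pore conductance to pore
    diameter through the Hille equation, infers excluded (projected) areas
    from blockade depth, computes reference projected-area distributions of
    molecular structures over an Euler rotation grid, and discriminates
    peptides by bootstrap kernel-density peak conductances. Includes peptide
    chemistry utilities (average mass, pH-dependent net charge, in-silico
    tryptic digestion).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, signal, jsonlite
Suggests: testthat (>= 3.0.0), bio3d, seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
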