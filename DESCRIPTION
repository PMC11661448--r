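Package: hdxstruct
Title: Differential Hydrogen-Deuterium Exchange Analysis with Structural
    Interface Mapping and Equilibrium Binding Fits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying differential hydrogen-deuterium exchange
    mass spectrometry (HDX-MS) experiments and relating the results to
    protein-protein interfaces. Converts isotope envelopes or centroid
    masses into per-peptide deuterium uptake, compares two states with the
    three-criterion significance filter (absolute uptake difference,
    percent exchange difference, and an unpaired t test), and summarises
    differences as Woods plots and per-residue maps. Computes
    solvent-accessible surface area (Shrake-Rupley), interchain contacts
    and buried surface area from PDB/mmCIF coordinates, and projects
    exchange differences onto structures through the B-factor field. Fits
    one-site equilibrium binding curves, compares mutant responses to wild
    type, and normalises two-channel bioluminescence reporter ratios. A
    synthetic-data module simulates two-state exchange kinetics with
    planted protection, isotope envelopes, toy interfaces with known
    ground truth, and dose-response curves, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
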