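---
title: "Methods: differential HDX-MS quantification, interface mapping, and binding fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential HDX-MS quantification, interface mapping, and binding fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxstruct)
library(dplyr)
```

This vignette is the package's account of its models and of the design
choices behind them: what is assumed, which knobs matter, what the
synthetic data does and does not emulate, and where numerical conventions
had to be fixed.

## The exchange model

Backbone amide hydrogens exchange with solvent deuterium. For amide $i$
with intrinsic rate $k_i$ (s$^{-1}$) and protection factor $P_i \ge 1$, the
probability of carrying a deuteron after labeling for time $t$ at a final
deuterium fraction $f_D$ is $f_D\,(1 - e^{-k_i t / P_i})$. A peptide's
expected uptake in deuterons is the sum over its *exchangeable* amides, and
its measured mass increase is that sum times 1.00628 Da (the $^2$H–$^1$H
mass difference). Binding-induced protection is modelled as a
multiplicative increase of $P_i$ over a residue range in the bound state,
so bound-state uptake is never larger than apo uptake at the planted
residues and identical elsewhere.

Assumptions worth keeping in mind:

* **EX2 kinetics.** Uptake is a smooth saturating function per residue;
  there is no bimodal (EX1) behaviour and the package deliberately does not
  try to detect it.
* **Phenomenological rates.** Intrinsic rates default to a log-uniform draw
  over $10^{-3}$–$10^{1}$ s$^{-1}$ rather than sequence-based reference
  rates, because all downstream statistics consume *relative* uptake
  differences between two states measured under the same conditions; the
  `rates` argument of `exchange_ground_truth()` is the hook for
  sequence-derived rates.
* **Back exchange.** The only correction is the known deuterium fraction of
  the labeling reaction, entering the percent-exchange denominator
  $N_\mathrm{ex} \times 1.00628 \times f_D$. Peptide-specific back-exchange
  during quench and chromatography is not modelled — it is unknown for the
  designs of interest, and guessing a value would silently distort percent
  thresholds.

### Exchangeable amides

`exchangeable_amides()` counts $N_\mathrm{ex}$ as peptide length minus the
first two residues minus prolines from position 3 onward. The N-terminal
two positions back-exchange too fast to retain label, prolines have no
amide hydrogen, and residues already excluded by the N-terminal rule are
not subtracted a second time. The skip count is configurable
(`skip_n_term`) because the convention differs between processing
platforms.

### Percent-exchange denominator

Percent exchange divides by the *theoretical* maximum
($N_\mathrm{ex} \times 1.00628 \times f_D$ Da). An alternative convention
divides by the maximum *observed* uptake; it is reachable by supplying the
observed maximum as the undeuterated reference, but the theoretical
denominator is the default because it needs no second experiment and keeps
the percent scale comparable across peptides.

## Isotope envelopes and centroids

`simulate_envelope()` builds the natural isotope distribution of a peptide
from its elemental composition by convolving per-element isotope
distributions on an extra-neutron grid (tracking both the probability and
the conditional mean mass per bin, with peaks below $10^{-12}$ relative
probability pruned), then convolves with a binomial distribution of
incorporated deuterons whose mean equals the requested uptake. The centroid
of a simulated envelope therefore equals the undeuterated centroid plus
$1.00628 \times D$ within $10^{-3}$ Da across the whole uptake range, which
is the package's round-trip contract between the envelope path and the
centroid-table path of `uptake_records()`. Charge conversion uses the
proton mass 1.007276 Da.

## The three-gate significance filter

`compare_states()` computes, per peptide and timepoint, the mean uptake
difference $\Delta D$ (bound $-$ apo; protection is negative), the
difference on the percent scale, and an unpaired two-tailed t-test on the
replicate uptakes. A peptide is significant when a single timepoint
simultaneously satisfies $|\Delta D| \ge 0.45$ Da, $|\Delta\%| \ge 5$, and
$p < 0.01$ (all three defaults configurable via
`significance_criteria()`). Requiring all gates *at the same timepoint* is
the stricter of the two readings of the usual phrasing and is the default;
`any_timepoint = FALSE` additionally demands every timepoint pass.

Choices fixed here:

* **Welch by default.** With triplicates, the equal-variance assumption of
  the classic Student test is untestable; Welch is safer and a
  `pooled = TRUE` option provides the classic variant. The per-cell
  p-values are computed vectorised from group summary statistics (the same
  Welch–Satterthwaite formulae as `stats::t.test`, which the test suite
  cross-checks to $10^{-12}$) so that thousand-dataset calibration runs
  stay fast.
* **Zero variance.** Noise-free fixtures make both groups constant, where
  the t statistic is undefined. The rule is deterministic: identical means
  give $p = 1$, different means $p = 0$ (perfect separation). This is what
  makes "noise 0 recovers exactly the overlapping peptides" a provable
  property rather than a numerical accident.
* **Boundary conventions.** The Da and percent gates are inclusive
  ($\ge$), the p gate exclusive ($<$), following the most explicit of the
  conventional phrasings ("$\ge$5%, $\ge$0.45 Da, $p < 0.01$").
* **No multiplicity correction by default.** The three-gate filter is the
  multiplicity control in this tradition — the effect-size gates dominate
  the error rate (see the calibration below); `adjust = "BH"` is available.
* **Summed quantities.** `sum_delta_d` adds $\Delta D$ over the shared
  timepoints; `sum_sd` adds the per-timepoint SD of the *difference*,
  propagated as $\sqrt{s_a^2/n_a + s_b^2/n_b}$, since the SD of a
  between-state difference is otherwise undefined.
* **Asymmetric designs.** Cells present in one state are dropped with an
  explicit report (attribute `dropped_cells`); peptides present in only one
  state remain visible but can never be significant; a single replicate
  yields `NA` p-values.

The test suite calibrates the filter on 1000 null datasets (12 peptides
tiling a 60-residue protein, four timepoints, triplicates, 0.02 Da
replicate noise — the scale at which a thousand-fold repetition stays
interactive) and requires the peptide-wise false-positive rate to stay
under the 1% bound given by the p gate alone; the 0.45 Da gate makes the
realised rate essentially zero at this noise level. Power is checked on a
planted 20-residue protected segment under the same noise: every peptide
whose exchangeable amides overlap the segment must be flagged, none other.

## What the synthetic data does not emulate

The generator reproduces the statistical structure the analysis assumes —
two states on a shared peptide/timepoint grid, saturating kinetics,
homoscedastic Gaussian replicate noise on the mass scale, a planted
protection segment with known extent. It does **not** emulate spectral
artifacts (overlapping envelopes, deconvolution errors), retention-time or
ionisation variability, peptide-specific back exchange, EX1 bimodality, or
correlated replicate noise. Passing tests therefore demonstrate
correctness of the quantification and inference machinery under the
declared model, not robustness to raw-spectrum pathologies, which are the
domain of upstream processing software.

## SASA, contacts, and buried surface area

`sasa()` implements Shrake–Rupley: each atom's van der Waals sphere is
expanded by the probe radius (default 1.4 Å, the conventional water probe),
sampled with a deterministic golden-spiral lattice (default 960 points —
doubling changes toy-model totals by under 0.5%, the package's convergence
test), and a point is inaccessible when strictly inside a neighbouring
expanded sphere. Radii default to a fixed published heavy-atom table
(C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å) with a configurable fallback for
exotic elements; hydrogens are stripped on reading. Exactly coincident
spheres are resolved by atom order — the earlier atom keeps the shared
surface — so duplicated atoms cannot double-count area (the numerical
tolerance on the tie is $10^{-8}$ Å$^2$ on squared distances).

`contacts()` reports residue pairs with any cross-side heavy-atom pair
within the cutoff, using a cell-list search whose results are tested to be
identical to brute-force all-pairs enumeration; 6 Å and 5 Å are the
conventional cutoffs for annotating interfaces, and the minimum atom
distance per pair is reported.

`buried_surface()` computes per-residue BSA as SASA of the residue's side
isolated minus SASA in the complex. The **total is reported under both
conventions** — summed over both partners (default headline number) and the
half value — because published interface areas are quoted under either
convention without always saying which; residues burying more than 30 Å²
(configurable) are annotated as key interface residues. Toy interfaces
with geometrically known interface membership verify that buried area
appears exactly on interface residues and balances between the two sides
within 20%.

`map_hdx_to_structure()` writes summed $\Delta D$ per covered residue into
the B-factor channel (mean over covering peptides; sentinel $-100$ for
uncovered residues, chosen to sit far outside any plausible ΔD scale while
fitting the PDB field width), counts peptide spans absent from the model as
uncovered rather than failing (disordered regions are expected), and
reports Jaccard overlap between HDX-significant residues and a supplied
interface set.

## Binding and reporter models

`fit_one_site()` fits $R(C) = R_\mathrm{max} C / (K_D + C)$ by
least squares (`nls`, port algorithm, parameters bounded positive).
Initialisation is deterministic — $R_{\mathrm{max},0}$ the maximum
response, $K_{D,0}$ the concentration nearest half-maximum — so refits are
reproducible; matched nonspecific background responses are subtracted
before fitting; non-convergence and degenerate inputs (all-zero responses)
return an explicit failure object with `converged = FALSE`. A warning is
raised when the concentration grid does not bracket the $K_D$ estimate,
since one-sided designs make $K_D$ and $R_\mathrm{max}$ nearly collinear.
"Normalised response" in plots means division by the fitted
$R_\mathrm{max}$; this normalisation constant is a convention and is
flagged as such here. The recovery test draws 200 titrations on an 8-point
log grid spanning 10–2500 nM with 2% noise and requires median relative
$K_D$ error under 10%.

`compare_max_response()` is Welch's test with the significance labels
ns $> 0.01$, `*` $< 0.01$, `**` $< 0.001$, `***` $< 10^{-4}$. Zero
within-group variance (constant toy replicates) is floored at
$\varepsilon_{\mathrm{mach}} \cdot \bar{x}^2$ with a warning so the test
stays defined and deterministic.

`bret_normalize()` computes per-well 530/485 ratios, normalises by the
mean ratio of the internal-control condition, and expresses fold changes
against the baseline-control condition; uniform channel gains cancel by
construction.

## Workflows, determinism, and I/O

`hdx_config()` collects run parameters (residue coordinates are 1-based
inclusive everywhere; tables are comma-separated UTF-8 with mandatory
headers and `.` decimals). `run_hdx_pipeline()` and
`run_interface_report()` compose the stages and write tables whose first
lines carry provenance (`# hdxstruct <version>`, `# config <hash> seed
<seed>`); numeric columns are rendered at fixed 6-decimal precision so
reruns with identical inputs are byte-identical. All randomness flows
through seeds recorded in that header. Schema violations report the
offending columns or rows and empty inputs fail loudly with a nonzero
status when run under `Rscript`.

## Known limitations

* No EX1/bimodal detection, no spectral deconvolution, no peptide
  identification — centroid masses or envelopes are the entry point.
* SASA is numerical; areas carry the lattice discretisation error (well
  below 0.5% of totals at the default 960 points, but per-atom values on
  tiny atoms are noisier).
* The one-site fit covers equilibrium dose–response only; kinetic
  sensorgram modelling ($k_{on}/k_{off}$) is out of scope and raw traces
  contribute only their maximal responses.
* Reproducing published interface areas for a specific deposited complex
  requires those coordinates; the package ships only synthetic structures
  and the corresponding test documents the expected file location.
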