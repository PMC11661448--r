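# hdxstruct

Quantitative analysis of differential hydrogen–deuterium exchange mass
spectrometry (HDX-MS) and its structural interpretation, for groups that
map protein–protein interfaces by combining exchange protection data,
buried-surface-area calculations on coordinates, and equilibrium binding
measurements.

## What it computes

**Differential HDX.** Backbone amides exchange with solvent deuterium at an
intrinsic rate `k_i` slowed by a protection factor `P_i`; a peptide's
expected uptake after labeling for time `t` at final deuterium fraction
`f_D` is

    D(t) = f_D * sum_i (1 - exp(-k_i * t / P_i))

over its exchangeable amides (the first two residues and prolines excluded).
Uptake is read off the intensity-weighted centroid of the isotope envelope;
percent exchange normalises by the theoretical maximum
`N_ex * 1.00628 * f_D` Da, the buffer deuterium fraction being the only
back-exchange control. Two states are compared per peptide and timepoint
with the three-criterion significance filter — |ΔD| ≥ 0.45 Da, |Δ%| ≥ 5 %,
and unpaired two-tailed t-test p < 0.01, all at the same timepoint — and
summarised as a Woods plot (summed ΔD against peptide center residue, error
as the summed per-timepoint SD of the difference) and a per-residue
protected/deprotected consensus.

**Structure.** Shrake–Rupley solvent-accessible surface area (probe 1.4 Å,
960 sphere points, published heavy-atom vdW radii), interchain contacts at
a configurable cutoff (6 Å / 5 Å conventions), per-residue and total buried
surface area `BSA = SASA(side alone) − SASA(complex)` (totals reported
summed over both partners and as the half value), and projection of
exchange differences onto coordinates through the B-factor field.

**Binding.** One-site specific binding `R(C) = R_max * C / (K_D + C)` by
nonlinear least squares with deterministic initialisation, Welch t
comparison of mutant versus wild-type maximal responses, and two-channel
(530/485 nm) reporter-ratio normalisation to internal and baseline
controls.

**Synthetic data.** Every stage has a seeded forward model with known
ground truth: planted protection segments with replicate noise, isotope
envelopes by polynomial convolution of elemental isotope distributions, toy
two-helix interfaces whose minimum interchain distance is exact, and
dose–response curves.

## Worked example

```r
library(hdxstruct)
library(dplyr)

seqs  <- paste(rep("ACDEFGHIKLMNQRSTVWYA", 6), collapse = "")
truth <- exchange_ground_truth(seqs, protected_range = 41:60,
                               protection_factor = 100,
                               replicate_sd = 0.02, seed = 7)
peps    <- tile_peptides(seqs, "TTC7B", seed = 3)
records <- bind_rows(simulate_uptake(truth, peps, "apo"),
                     simulate_uptake(truth, peps, "bound"))

cmp   <- compare_states(records, state_a = "apo", state_b = "bound")
woods <- woods_summary(cmp)
filter(woods, significant)
#> # A tibble: 6 × 8
#>   protein start   end sequence     center_residue sum_delta_d sum_sd significant
#> 1 TTC7B      31    42 MNQRSTVWYAAC           36.5       -1.81 0.0492 TRUE
#> 2 TTC7B      36    49 TVWYAACDEFG…           42.5       -7.31 0.0538 TRUE
#> 3 TTC7B      41    50 ACDEFGHIKL             45.5       -5.65 0.0585 TRUE
#> 4 TTC7B      46    60 GHIKLMNQRST…           53        -11.7  0.0534 TRUE
#> 5 TTC7B      51    61 MNQRSTVWYAA            56         -9.32 0.0767 TRUE
#> 6 TTC7B      56    65 TVWYAACDEF             60.5       -4.46 0.0700 TRUE
```

Exactly the peptides whose exchangeable amides overlap the planted
protected segment (residues 41–60) are flagged, all with negative summed
ΔD — less exchange upon binding, i.e. protection. `autoplot(woods)` draws
the Woods plot; `residue_consensus(cmp)` marks residues 31–65 protected
(the union of the flagged peptide spans).

```r
curve <- simulate_dose_response(23.5, 1, c(10, 25, 62, 156, 391, 977, 2500),
                                noise_sd = 0.01, seed = 2)
fit_one_site(curve)
#> <hdx_binding_fit> kd = 23.58 +/- 0.74 nM, rmax = 1.002 +/- 0.006 (n = 7)

toy <- make_toy_interface(n_res_per_chain = 12, separation = 3.5)
buried_surface(toy$model, "A", "B", n_points = 480)
#> <hdx_interface> A vs B
#>   total BSA (both sides): 179.1 A^2  (half: 89.6)
#>   contacts (cutoff 6 A): 8 residue pairs; residues with BSA > 30 A^2: 0
```

The titration recovers the planted K_D of 23.5 nM within its standard
error, and the toy interface buries area only on the residues placed at the
contact surface. `run_hdx_pipeline()` and `run_interface_report()` compose
these stages into the two end-to-end workflows, reading and writing CSV
tables with provenance headers (see the methods vignette).

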