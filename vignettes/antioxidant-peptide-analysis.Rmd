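---
title: "Antioxidant peptide analysis with aoxpep: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antioxidant peptide analysis with aoxpep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoxpep)
```

This vignette is the package's account of its science: what each component
models, which parameters matter and why their defaults are what they are,
what the simulators do and do not emulate, and where genuinely open design
questions were settled.

## 1. The integral antioxidant score

A peptide's predicted antioxidant ranking is

$$I = \left[\frac{\sum_i E_i}{n}\right] \times \frac{10}{N}$$

with $E_i$ the effects (±1) of matched empirical motifs, $n$ the number of
redox-active residues (Tyr, Trp, Met, Cys, His), and $N$ the peptide length.
The motif table (`aox_rules()`) is assay-specific because the two model
radicals probe different chemistry: the peroxyl radical (ORAC) oxidizes
thioether sulfur, so a C-terminal Met — whose cation radical can discharge
by decarboxylation — is favourable; the ABTS cation radical (TEAC) is
quenched mainly through single-electron transfer from phenol/indole systems,
favouring N-terminal Tyr or Trp with a free α-amino group. Synergy motifs
(Trp-Tyr for the peroxyl radical; Tyr-His, His-Tyr, Met-Tyr for ABTS)
capture intramolecular electron transfer between redox centres, and
ionogenic-neighbour motifs capture the influence of charged side chains on
an adjacent tyrosine.

Three conventions had to be fixed where the formula alone is ambiguous:

- **Effect attribution.** $\sum_i E_i$ sums over *matched motif
  occurrences*, each counted once. The alternative — attributing effects to
  individual redox residues — makes a two-redox-residue motif like Trp-Tyr
  ambiguous (which residue "owns" the effect?). The per-match reading keeps
  dipeptide scores independent of that choice; the full match list is
  returned in the `matches` column so the attribution is auditable.
- **The redox count $n$ uses the union set** {Y, W, M, C, H} for both
  assays. The TEAC rule set itself references Met (Met-Tyr) and His
  (Tyr-His/His-Tyr) even though these residues have no free-amino-acid TEAC
  activity; an assay-specific $n$ would leave those motifs dividing by a
  count that excludes one of their members.
- **$n = 0 \Rightarrow I = 0$.** The formula is undefined without
  redox-active residues; zero encodes "no radical chemistry available".
- **Motif position.** Pair rules match anywhere in the sequence, not only
  at the termini of a dipeptide. The rules were derived from dipeptides, so
  applying them internally in longer peptides is an extrapolation; it is the
  natural screening reading and is documented as such. Terminal rules match
  positions 1 and $N$ only (a single residue is both termini).
- **Overlapping matches all count** (e.g. `KYH` under TEAC matches both
  Lys-Tyr and Tyr-His).

`I` is a dimensionless ranking score only; the package deliberately offers
no conversion from `I` to µmol TE/µmol. Ranking ties are broken
lexicographically by sequence so ranked output is deterministic.

## 2. Descriptor calculus

`compute_descriptors()` consumes tabulated frontier-orbital energies (eV)
and optional total energies (Hartree) — it never runs electronic-structure
calculations. Definitions:

| descriptor | definition | units |
|---|---|---|
| electronegativity χ | −(E_HOMO + E_LUMO)/2 | eV |
| hardness η | (E_LUMO − E_HOMO)/2 | eV |
| electrophilicity ω | χ²/(8η) (default) or χ²/(2η) | eV |
| Koopmans IP (IPo) | −E_HOMO | eV |
| adiabatic IP (IPe) | [E(cation) − E(neutral)] × 27.2114 | eV |
| gap | E_LUMO − E_HOMO | eV |
| BDE | [E(radical) + E(H) − E(parent)] × 627.509 | kcal/mol |

The ω default deserves a note: the textbook Parr electrophilicity is
χ²/(2η), but the packaged reference descriptor table for the five
redox-active amino acids (`amino_acid_descriptors()`) is internally
consistent only with χ²/(8η) — all five tabulated ω values are reproduced by
that form and none by the textbook form. The package therefore defaults to
the table-consistent convention and exposes `omega_mode = "standard"` for
the Parr definition (exactly 4× larger). Similarly, the tabulated His gap
(5.79 eV) is slightly inconsistent with its tabulated hardness
(2.889 eV ⇒ gap 5.778 eV); the reference table ships the printed values
unchanged and the reproduction tests use a 0.02 eV tolerance that
accommodates the discrepancy rather than "correcting" it.

The hydrogen-atom energy entering the BDE defaults to −0.5 Hartree (the
exact nonrelativistic value) and is configurable, since DFT functionals
place E(H) slightly away from −0.5 and the source of a user's energies may
differ.

Mulliken-charge attack-site analysis (`max_density_atoms()`) ranks atoms by
ascending charge — the most negative charge marks the highest local electron
density, the preferred target of electrophilic/radical attack. Atoms within
`tie_epsilon` (default 0.005 e, half a unit in the last printed digit of
typical charge tables) of the minimum are reported together, most negative
first, with alphabetical order breaking exact ties.

## 3. Dipeptide additivity

The additive expectation for a dipeptide is
$AOC_{theo} = a_N(\text{res}_1) + a_C(\text{res}_2)$, with terminal
contributions from `terminal_contributions()`. Each entry carries a
provenance flag: `printed` values come directly from measured means
(TEAC N-/C-terminal Tyr 4.81/1.70; ORAC C-terminal Met 0.45 µmol TE/µmol),
`derived` values follow by arithmetic (e.g. the TEAC Trp terminals 3.30 and
2.60 read off Trp-Met and Met-Trp, since Met contributes nothing against
ABTS; the ORAC N-terminal Met 0.39 is the C-terminal value less the
observed 20% penalty), and `figure` values are coarse bar-chart
approximations (the ORAC Tyr and Trp terminals). Figure-provenance values
are suitable for classification, which is tolerance-based, but must never
enter exact-equality checks — the test suite enforces this convention by
only asserting exact sums built from printed/derived entries.

A measured value within `rel_tol` of the additive expectation is
`additive`; above, `synergic`; below, `infra_additive`. The default
`rel_tol = 0.10` sits midway in the band (≈0.034, 0.13) bracketed by the
reference calls — a +3.4% deviation called additive and a −13% deviation
called infra-additive — so any tolerance in [0.05, 0.12] reproduces those
calls; the tests sweep that whole band. When measurement SDs are available,
the additive band widens to `max(rel_tol·theo, 2·combined SD)` so that
classification is never finer than the measurement uncertainty. Degenerate
inputs (theoretical ≤ 0) raise an error rather than returning a label: a
relative deviation from a non-positive expectation is meaningless.

## 4. Assay quantification

Both pipelines share the same skeleton: per-well response → trolox
calibration by ordinary least squares → AOC =
((response − intercept)/slope)/concentration, in µmol TE per µmol.

- **TEAC** response is the OD₇₃₄ decline at a single read time
  (default `t_read = 40.5` min, the end of the standard registration
  window) relative to the mean control well, with linear interpolation
  between measured time points. An endpoint difference was chosen over an
  integrated response because the calibration regresses *optical density*
  against trolox concentration; the read time is exposed for instruments
  with other windows.
- **ORAC** response is the net area under the fluorescein decay curve:
  each well's curve is normalized to its first reading (standard net-AUC
  practice, making the response robust to well-to-well gain differences),
  integrated by the trapezoidal rule, and referenced to the mean blank AUC.

Times are minutes internally; `time_unit = "s"` converts on input. Final
in-well concentrations are the user's responsibility (plate layouts vary and
published dilution descriptions are often ambiguous); the helper
`final_concentration()` covers the common 20 µL-into-200 µL layout.

## 5. The simulators, and what passing tests mean

The simulators exist so that every stage — curve integration, calibration,
inversion, screening — can be tested end to end with known ground truth.

`sim_orac_plate()` uses a protected-fraction mixture: a fraction
$p = \alpha\,c\,TE$ of the fluorophore decays with a fixed lag $L$
(`lag_full = 30` min) while the rest decays immediately at rate $k$
(`decay_rate = 0.25`/min over a 60-min window sampled every minute). Because
the signal is affine in $p$ at every time point and trapezoidal integration
is a linear functional, the net AUC is *exactly* linear in TE-equivalent
concentration — a noise-free plate round-trips through `orac_aoc()` to
machine precision, giving a sharp correctness oracle. (A lag-*shift* model,
with the lag duration proportional to antioxidant amount, looks more like
textbook ORAC kinetics but its sampled net AUC is only approximately linear:
the kink between grid points contributes a lag-dependent trapezoid error, so
it cannot serve as an exact oracle.) `sim_teac_plate()` declines toward
$OD_0 - \gamma\,c\,TE$ with saturating kinetics, again exactly linear in
$TE\cdot c$ at every time point. Default sample TE values mirror measured
free-amino-acid AOCs (Tyr 1.02/3.38, Trp 2.79/3.33 µmol TE/µmol); calibrants
span 1–10 µM as in the standard trolox series. Noise is multiplicative
Gaussian (`noise_sd` as a fraction of signal), preserving signal positivity
and leaving the linear pipeline unbiased.

These are test-harness response models, not radical-kinetics mechanisms:
they share with real plates the layout, the linear response in trolox
equivalents and the noise scale, but not AAPH decomposition kinetics,
fluorescein photobleaching, gain drift, or saturating antioxidant chemistry.
A passing round-trip therefore validates the *quantification arithmetic*,
not the chemistry of any particular plate.

`sim_descriptor_table()` draws descriptors with prescribed correlations to
activity through a single-factor Gaussian construction
$x_j = \rho_j z + \sqrt{1-\rho_j^2}\,\varepsilon_j$ (activity $= z$), a
valid factorization of the implied correlation matrix for any
$|\rho_j| \le 1$. Default targets (−0.819, −0.874, −0.818 for IPe, χ, ω)
mirror the inverse descriptor–activity correlations reported for methionine
dipeptides with non-ionogenic partners; those reported coefficients are used
only as simulation targets, never asserted against, because the underlying
measurement table is not reproducible here. All simulators are pure
functions of their arguments with explicit integer seeds.

## 6. The correlation screen

`pearson_cor()` reports the product-moment r with a two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. Two-sided was
chosen because the screening context states only a significance level, and
a screen should not presuppose the direction of each descriptor's effect.
No multiple-testing correction is applied by default (matching a
per-descriptor report over a handful of descriptors); `adjust =
"bonferroni"` is available. Peptides containing Asp/Glu/Lys/Arg are excluded
by default (`filter_ionogenic()`): in the gas phase their descriptors are
dominated by the charged side chain rather than the redox-active residue,
and solvation reverses the shifts, so gas-phase descriptors of ionogenic
peptides do not transfer to aqueous assays. A constant descriptor column is
reported as undefined (`NA`) without failing the rest of the screen.

## 7. Numerical choices and problem sizes

- Trapezoidal integration via `pracma::trapz`; OLS via `stats::lm`;
  exact-line calibrations recover slope/intercept to ~1e-15 and the
  noise-free assay round-trip tests assert ≤1e-9 relative error.
- Property tests run at deliberately modest sizes chosen to make sampling
  error negligible relative to the asserted bounds: the dipeptide oracle
  sweep covers all 121 ordered pairs over the 11-letter relevant alphabet;
  the null-distribution check of the correlation p-value uses n = 14 with
  10,000 replicates (rejection rate asserted within ±0.01 of 0.05, ≈4.6
  binomial SDs); noisy-recovery bias is averaged over 100 seeds at 1%
  noise; large-n correlation convergence uses n = 10,000.
- Random-draw tests fix their seeds; everything asserted is reproducible.

## 8. Known limitations

- The rule table encodes motifs observed in dipeptides; applying them to
  longer peptides is an extrapolation, and `I` has no calibrated mapping to
  measured AOC.
- Descriptors are consumed as tabulated gas-phase values; solvent effects —
  known to reverse some ionogenic shifts — are not modelled, which is one
  reason the ionogenic exclusion exists.
- The assay simulators are linear-response harnesses (see §5); real plates
  can violate linearity at high antioxidant loads.
- Terminal contributions for some residue/assay combinations are
  figure-derived approximations and carry that provenance flag; exact
  downstream conclusions should not be built on them.
- Cys terminal contributions are absent from the packaged table (no
  measured dipeptide anchors them); requesting them raises an explicit
  lookup error by design.
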