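---
title: "Methods: post-DFT analysis of the benzil dye series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-DFT analysis of the benzil dye series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benzilkit)
library(dplyr)
library(purrr)
```

benzilkit post-processes electronic-structure summaries of benzil (BZL) and
its para-substituted dimethyl (DMB), difluoro (DFB), dichloro (DCB) and
dibromo (DBB) analogues. Everything downstream of the quantum-chemistry
engine is in scope — reactivity descriptors, solar-cell figures of merit,
NLO scalars, vibrational agreement statistics, torsional barriers, docking
summaries and the descriptor-to-binding-energy regression. Running DFT/TD-DFT
itself, geometry optimisation and docking pose generation are out of scope:
the package consumes their tabulated outputs.

## Conceptual-DFT descriptors

From a vertical ionisation potential and electron affinity (eV),

$$\chi = \tfrac{IP+EA}{2},\quad \mu = -\chi,\quad \eta = \tfrac{IP-EA}{2},
\quad S = \tfrac1\eta,\quad \omega = \tfrac{\mu^2}{2\eta}.$$

`compute_descriptors()` keeps full double precision so the identities
$\chi = -\mu$, $S\eta = 1$, $2\eta\omega = \mu^2$ and $IP-EA = 2\eta$ hold
to 1e-12 and can be property-tested.

IP and EA are stored independently of the orbital energies. Although
Koopmans-style reasoning equates IP with $-E_\mathrm{HOMO}$, published
descriptor tables are routinely computed from a different state (e.g.
ΔSCF), and for this series the descriptor table is demonstrably *not*
derivable from the orbital-energy table (BZL: IP 8.748 eV vs
$-E_\mathrm{HOMO}$ = 6.596 eV). Keeping both inputs lets every table be
reproduced simultaneously. Two gap notions are likewise exposed under
distinct names: `orbital_gap()` ($E_\mathrm{LUMO}-E_\mathrm{HOMO}$) and
`gap_ipea` ($IP-EA$).

### Reproducing 3-decimal published tables

A subtlety worth documenting because it generalises: the published
descriptor table propagates display rounding. Its softness and
electrophilicity columns are computed from χ and η *after* those were
rounded to three decimals — BZL's ω cell (20.441) equals
$7.407^2/(2\cdot1.342)$, while the full-precision value is 20.446. Decimal
halves are rounded half-away-from-zero (7.4065 → 7.407), which binary
floating point misrepresents, so the emulation nudges exact halves with a
1e-9 epsilon.
`reactivity_descriptors(style = "printed")` reproduces that chain; the
default `style = "exact"` never rounds and is what all other computations
consume. The printed style exists purely so published cells can be
verified to their stated precision.

```{r}
benzil_table("descriptors") |>
  select(id, ip, ea) |>
  reactivity_descriptors(style = "printed")
```

## Photovoltaic modelling

For each dye the chain is
$LHE = 1-10^{-f}$,
$E(0,0) = 1240/\lambda_{max}$ (eV, λ in nm),
$E_{dye} = -E_\mathrm{HOMO}$,
$E^*_{dye} = E_{dye} - E(0,0)$ and
$\Delta G_{inject} = E^*_{dye} + E_{CB}$ with $E_{CB} = -4.00$ eV for
TiO~2~. A more negative $\Delta G_{inject}$ means more spontaneous electron
injection into the conduction band; `select_best_sensitizer()` ranks on it
with LHE, then id, as tie-breaks.

Numerical choices:

* The eV·nm constant defaults to the conventional **1240** rather than the
  exact $hc$ = 1239.84193: the series' published excitation energies
  reproduce to six decimals under 1240 (e.g. $1240/286.99 = 4.320708$) and
  not under the exact constant, which remains available via the `constant`
  argument.
* The sign convention $\Delta G = E^*_{dye} + E_{CB}$ (with $E_{CB}$
  negative) is stated explicitly because the literature mixes several
  equivalent forms; `--ecb`/`e_cb` overrides the band energy.
* One published LHE cell (DBB, 0.9079) is a truncation of the computed
  0.907955; the package reports the computed value, which agrees with the
  printed one to the package-wide 1e-3 cell tolerance.

```{r}
pv <- benzil_molecules() |>
  mutate(f = map_dbl(excitations, ~ .x$f[1]),
         lambda_max_nm = map_dbl(excitations, ~ .x$lambda_nm[1])) |>
  photovoltaic_table()
pv |> select(id, lhe, e00, e_dye_star, dg_inject)
select_best_sensitizer(pv)
```

## NLO scalars

Scalar invariants follow the standard conventions of quantum-chemistry
outputs: the contracted vector norm for the first hyperpolarizability
($\beta_i = \beta_{iii} + \beta_{ijj} + \beta_{ikk}$ over the
Kleinman-symmetric set, then $\|\beta\|$), the isotropic fifth-average for
the second hyperpolarizability, and the diagonal mean for the
polarizability. The combination rules are not stated alongside the
published scalar table, so tensor paths are exercised against
explicit-summation and explicit-rotation oracles on synthetic tensors, and
rotation invariance is asserted to 1e-9.

Unit conversions use 1.4819e-25 (α), 8.6393e-33 (β) and 5.0367e-40 (γ) esu
per atomic unit. The urea reference defaults to $\beta_{urea} =
0.13\times10^{-30}$ esu — the unique two-significant-figure value
consistent with all five published fold-ratios (15, 31, 29, 52, 64) — and
is configurable. Fold-ratios are rounded half away from zero, the
convention behind "x times urea" statements.

## Vibrational agreement

Calculated harmonic wavenumbers are scaled by the standard B3LYP factor
0.9613 (`apply_scaling()`, idempotence-guarded: scaling an already scaled
table errors). The packaged assignment tables store the calculated column
already scaled — their C–H stretches near 3100 cm⁻¹ are incompatible with
unscaled harmonic values — so the scaling operation serves raw-input
workflows.

Pairing is assigned-mode by default (row-wise, as published assignment
tables are laid out); nearest-mode pairing matches greedily by ascending
distance within a 30 cm⁻¹ default window, each band used at most once.
Scaling and pairing do not commute unless the window scales too, so the
supported order is scale first, then pair — asserted by a regression test.
RMSD is computed per technique (IR and Raman separately). The exact
row-inclusion rules behind the published RMSD list are unstated;
recomputation from the packaged transcriptions lands near but not exactly
on some published values (BZL IR: 5.02 vs 5.1), so these are tolerance
checks (±0.3 cm⁻¹ for the BZL IR anchor), not exact targets.

## Torsion profiles

The dihedral of interest is the inter-ring C4–C6–C5–C3 twist. Raw scan
energies for the series were not published — only barrier heights and
approximate extrema angles — so those ship as metadata
(`benzil_table("torsion_metadata")`) and the module's correctness is
established on synthetic cosine wells
$A/2\,(1-\cos k(\theta-\theta_0))$ where barrier and extrema are known in
closed form. Extrema are reported at grid resolution (10° default, matching
the "at about 40°" precision of scan figures), ties broken by smallest
angle; barriers are max − min and thus shift-invariant. Hartree inputs are
converted at 2625.50 kJ/mol. The published extrema are stated
inconsistently per molecule (130° vs 140° minima); the metadata records
them as printed without resolving.

## Docking summaries and QSAR

Score tables (global energy, attractive/repulsive vdW, atomic contact
energy per ranked conformation) are validated on parse: ranks 1..n without
gaps, nonnegative repulsive terms, rank 1 at the block-minimum global
energy. Units are opaque score units — no kcal/mol is implied. "High"
atomic contact energy in prose is read as most negative (stabilizing), and
because rank-1 ACE and block-minimum ACE genuinely differ (3WMT: −8.89
under BZL vs −9.73 under DMB at rank 10), `best_complex()` exposes both
statistics rather than baking in one reading. One related caveat: for the
2H4Z receptor the published prose names DCB as best by global energy while
the score table's rank-1 minimum sits under DMB (−32.38 vs −25.92); the
package follows the table.

The QSAR response is *built from the docking pipeline* — the rank-1 ACE
vector per receptor equals the published binding-energy columns
cell-for-cell — rather than transcribed twice. The design is binding
energy on IP, EA, S and ω plus intercept; χ, μ and η are excluded as exact
linear/derived combinations of IP and EA (they would make the design
singular). With five molecules the system is square: it is solved exactly
via QR when nonsingular (singularity raises an error naming the collinear
columns; condition numbers above 1e8 warn), so the fit interpolates the
responses, which is precisely the property the published table satisfies.
The published integer coefficients are kept only as a comparison fixture:
applied directly to the descriptor rows they miss the binding energies by
>10 score units (integer rounding destroys an exact interpolation), and
`qsar_printed_report()` quantifies that discrepancy and the per-coefficient
sign agreement instead of asserting agreement.

## Synthetic data

Generators (`generator_config()` and friends) exist so every pipeline
stage is testable with controlled ground truth and no external downloads.
Defaults were fixed once to mirror the study conditions: five molecules,
IP in [8.0, 8.8] eV strictly above EA in [5.5, 6.2] eV, absorption maxima
in [260, 300] nm with oscillator strengths in [0.5, 1.1], vibrational
observation noise σ = 5 cm⁻¹ (the magnitude of the study's IR RMSDs, with
n = 200 modes so the RMSD estimator concentrates within ~15% of σ),
two-fold torsional wells of 8–18 kJ/mol on the 10° grid, and docking
blocks of 10 conformations. Each generator draws from its own named
pseudo-random stream derived from the seed, so adding a generator never
perturbs existing outputs, and a fixed config regenerates byte-identical
fixtures.

What synthetic data does *not* emulate: correlated mode assignments,
anharmonic or Fermi-resonance structure in spectra, non-cosine torsional
profiles with multiple inequivalent wells, and correlated docking scores.
Passing the property suite therefore demonstrates the arithmetic and the
invariances, not robustness to those real-data features.

## Problem sizes and runtime

All reproduction targets are desk-scale: five molecules, 150 docking rows,
at most 46 vibrational rows per molecule, 36-point torsion grids, and
property sweeps of 20–200 random draws. The whole test suite and the
acceptance script each run in seconds on one CPU.

## Known limitations

* The printed-style descriptor table emulates one plausible rounding chain;
  other publications may propagate rounding differently.
* Assigned-mode pairing trusts the row alignment of the transcribed tables;
  the published RMSD list is reproduced only approximately (see above).
* Torsion analysis is grid-level by design — no interpolation between scan
  points — so recovered extrema inherit the grid resolution.
* Only static (frequency-independent) NLO scalars are handled.
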