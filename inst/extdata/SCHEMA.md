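# Fixture schemas

Units are part of the schema, never guessed: energies in eV, wavelengths in
nm, wavenumbers in cm^-1, torsion-scan energies in kJ/mol (hartree accepted
on load with conversion 2625.50 kJ/mol per hartree), dipoles in Debye,
polarizability scalars in esu at the scale encoded in the column suffix
(`alpha_esu23` = alpha / 1e-23 esu, `beta_esu30` = beta / 1e-30 esu,
`gamma_esu37` = gamma / 1e-37 esu). Docking scores are opaque "score units".

## benzil_series.json

Top-level object with a `molecules` array. Each molecule:

| field        | type   | constraint                                   |
|--------------|--------|----------------------------------------------|
| id           | string | short label, unique (BZL, DMB, DFB, DCB, DBB)|
| name         | string | free text                                    |
| e_homo       | number | eV, `e_homo < e_lumo`                        |
| e_lumo       | number | eV                                           |
| ip_vertical  | number | eV, stored independently of `-e_homo`        |
| ea_vertical  | number | eV, `ip_vertical > ea_vertical`              |
| dipole_debye | number | >= 0                                         |
| excitations  | array  | objects with `lambda_nm > 0`, `f >= 0`, and a `composition` array of `{donor, acceptor, weight}` with each weight in (0, 100] and weights summing to <= 100 (minor contributions may be omitted) |
| nlo          | object | scalar NLO block (`mu_debye`, `alpha_esu23`, `beta_esu30`, `gamma_esu37`) and/or tensor components in atomic units |
| method_note  | string | provenance of the electronic-structure data  |

`ip_vertical`/`ea_vertical` are deliberately independent inputs: the study's
descriptor table is not derivable from its orbital-energy table, so both are
stored as printed.

## Flat CSV tables

All CSVs carry one `#` comment line naming the source table and units,
then a header row. Files:

- `table1_photovoltaics.csv`: printed photovoltaic table (reproduced by the
  package from `f`, `lambda_max_nm`, `e_homo`, `e_lumo`, `e_cb` alone).
- `table2_descriptors.csv`: printed reactivity descriptors.
- `table3_nlo.csv`: printed NLO scalars.
- `table4_docking.csv`: long format, columns `receptor, ligand, rank,
  global_energy, attractive_vdw, repulsive_vdw, ace`; ranks 1..10 per block,
  blocks sorted by `global_energy` ascending in rank.
- `table5_qsar.csv`: descriptors plus per-receptor binding energies
  (`be_<receptor>`); the BE columns equal the rank-1 `ace` of the matching
  `table4_docking.csv` block.
- `qsar_printed_coefficients.csv`: the study's printed integer regression
  coefficients (comparison only).
- `torsion_metadata.csv`: printed barrier heights and extrema angles (the
  raw scan energies were not published).
- `vib_<ID>.csv`: per-molecule vibrational table, columns `calc, ir_int,
  raman_act, obs_ir, obs_raman, assignment`; empty cells mean no band
  reported. The `calc` column is already scaled (factor 0.9613 applied
  upstream). Assignment labels use ASCII u/d/g/t for stretching, in-plane
  deformation, out-of-plane deformation and torsion.

## Torsion profile CSV

`angle_deg,energy` data rows after one comment line of the form
`# unit: kJ/mol` (or `# unit: hartree`). Angles form a strictly increasing
grid in [0, 360).
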