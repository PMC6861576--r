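Package: benzilkit
Title: Post-DFT Reactivity, Photovoltaic, NLO, Vibrational, Docking and
    QSAR Analysis for Benzil-Type Dyes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for electronic-structure summaries of benzil and
    its para-substituted analogues (dimethyl, difluoro, dichloro, dibromo).
    Computes conceptual-DFT global reactivity descriptors (electronegativity,
    chemical potential, hardness, softness, electrophilicity index) from
    vertical ionisation potentials and electron affinities; models
    dye-sensitised solar-cell performance (light-harvesting efficiency,
    vertical excitation energy, excited-state oxidation potential and
    electron-injection free energy against a TiO2 conduction band); reduces
    hyperpolarizability tensors to standard scalar invariants with
    atomic-unit to esu conversion and urea-referenced ratios; compares scaled
    calculated vibrational wavenumbers with observed IR/Raman bands via RMSD;
    analyses torsional potential-energy profiles (extrema, barrier heights);
    summarises ranked protein-ligand docking score tables; and fits exact or
    least-squares linear QSAR models of binding energy on reactivity
    descriptors. Ships transcriptions of the study's data tables as
    plain-text fixtures plus seeded synthetic generators for every input
    kind.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
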