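Package: clampmap
Title: Biophysical Mapping of TPR Carboxylate-Clamp Peptide Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for NMR- and calorimetry-based mapping of
    protein-peptide interactions such as the binding of a TPR-domain
    carboxylate clamp to a C-terminal peptide. Tracks assigned amide peaks
    across fast-exchange titrations, computes combined chemical shift
    perturbations, fits 1:1 binding isotherms for dissociation constants
    with bootstrap uncertainties, profiles backbone dynamics from
    heteronuclear NOE intensity ratios, maps paramagnetic relaxation
    enhancement broadening onto structures, fits one-site isothermal
    titration calorimetry thermograms with full thermodynamic
    interconversion, and converts perturbation plus solvent-accessibility
    filters into ambiguous interaction restraints for data-driven docking.
    A seeded synthetic-data module generates titrations, intensity tables,
    thermograms and toy structures so the whole pipeline is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
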