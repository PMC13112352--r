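Package: chargereg
Title: Sequence-Specific Charge Regulation and Conformation of Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variational mean-field theory for charge-regulating intrinsically
    disordered proteins and weak polyelectrolytes. Solves a set of coupled
    self-consistent equations for a renormalized Kuhn length (uniform expansion
    model) and residue-specific ionization mean-fields under Debye-Hueckel
    screened electrostatics on a Gaussian chain, in the constant-pH ensemble.
    Provides titration sweeps, per-residue ionization profiles, net charge,
    end-to-end distances and isoelectric points for arbitrary amino-acid
    sequences, generators for E/K model polyampholytes spanning a range of
    charge blockiness, and independent quadrature and Monte Carlo oracles for
    validating the interaction kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'erfcx.R'
    'AllClasses.R'
    'AllGenerics.R'
    'chargereg-package.R'
    'core-model.R'
    'sequence-spec.R'
    'kernels.R'
    'solver.R'
    'observables.R'
    'io.R'
    'cli.R'
    'sequences.R'
    'oracles.R'
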