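Package: HcAbStab
Title: Structure-Based Stability Assessment and Variant Design for
    VHH-Fc Heavy-Chain Antibodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An in silico developability toolkit for VHH-Fc heavy-chain
    antibodies. Computes solvent-accessible surface area (Shrake-Rupley),
    hydrophobic and ionic surface patches, net charge and isoelectric
    point, spatial aggregation propensity (SAP) and the developability
    index (DI), classifies disulfide reduction propensity from corrected
    redox potentials, analyses docked dimer pose ensembles for binding
    modes and per-residue interface preference, applies solvent-exposure
    rules for methionine/tryptophan oxidation liability, combines the
    evidence into a stability hotspot report, enumerates rule-based
    stabilising variants, and screens calculated structural features
    against experimental stability attributes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'HcAbStab-package.R'
    'data-tables.R'
    'charge.R'
    'structure.R'
    'fixtures.R'
    'geometry.R'
    'sasa.R'
    'hotspots.R'
    'interfaces.R'
    'redox.R'
    'sap.R'
    'stability.R'
    'variants.R'
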