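Package: prioMD
Title: Family-Based Variant Prioritization and Molecular Dynamics Trajectory Analytics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for candidate-gene discovery in dominant
    Mendelian families. Stage one filters and prioritizes annotated exome
    variants: a filtration cascade (consequence, zygosity, minor allele
    frequency), pedigree co-segregation with an explicit phenocopy allowance,
    and consensus deleteriousness ranking over SIFT, PolyPhen-2,
    MutationTaster, CADD, Condel and GERP++ conservation. Stage two computes
    molecular-dynamics trajectory observables from first principles: Kabsch
    superposition, RMSD and per-residue RMSF, radius of gyration,
    Shrake-Rupley solvent-accessible surface area, essential-dynamics
    covariance PCA, and Boltzmann-inversion free-energy surfaces with
    metastable-state counting. Seeded synthetic generators for pedigrees with
    a planted causal variant and for trajectories with controllable dynamics
    make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
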