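Package: blockpol
Title: Building-Block Prediction of Protein Dipole Moments and Polarizabilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the electrical properties of protonated protein
    structures from a database of transferable building-block properties.
    Residues are decomposed into backbone, side-chain and terminal blocks
    carrying stored dipole vectors and polarizability tensors; ionizable
    groups receive Henderson-Hasselbalch fractional charges at a chosen pH
    (with an isoelectric-point solver); coordinated Na+/Cl- ions are detected
    by distance criteria and neutralize their residues; point-charge fields
    correct the block ("core") dipoles; and an Applequist dipole interaction
    model with Thole-style damping corrects dipoles and polarizabilities for
    the surrounding environment (ions and waters inside an inflated
    minimum-volume enclosing ellipsoid). Includes a seeded synthetic
    block-property database and ideal-geometry peptide fixture generators,
    plus the 70-member NaCl ion-pair configuration enumerator and sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
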