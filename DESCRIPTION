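Package: ssefold
Title: RNA Tertiary Structure Assembly from Smallest Secondary Elements
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts RNA three-dimensional structure from sequence and
    secondary structure by decomposing the secondary structure into its
    smallest secondary elements (stems, hairpin, bulge, internal and junction
    loops), assembling per-element 3D templates by Kabsch superposition over
    shared closing base pairs, generating missing loop templates de novo by a
    bi-residue fragment method or by distance geometry, refining models with
    restraint-guided simulated-annealing Monte Carlo (pseudoknot base pairs
    are expressed as distance restraints), and selecting representative
    models by RMSD k-medoid clustering with a knowledge-based score. Ships a
    synthetic fixture generator (ideal helices and generated loops) so the
    whole pipeline runs without any external template database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, bio3d
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'ssefold-package.R'
    'nucgeom-data.R'
    'utils.R'
    'AllClasses.R'
    'geometry.R'
    'secstruct.R'
    'nucgeom.R'
    'conformation.R'
    'templates.R'
    'loopgen.R'
    'assembler.R'
    'optimizer.R'
    'analysis.R'
    'fixtures.R'
    'io.R'
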