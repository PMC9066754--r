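Package: cycpepgen
Title: Template-Based Conformer Generation for Disulfide-Cyclized Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds length-stratified libraries of disulfide-closed cyclic
    backbone fragments mined from PDB-format structures, clusters them with a
    length-dependent backbone-RMSD cutoff, and assembles full-atom conformer
    ensembles for peptides cyclized by one disulfide bond.  Backbone templates
    are drawn with a probability that combines BLOSUM62 sequence similarity
    and crystallographic resolution; side chains come from a rotamer library
    and non-cyclic termini are grown residue by residue in internal
    coordinates.  Includes ensemble diversity filtering, Kabsch superposition,
    Calpha/backbone/heavy-atom RMSD evaluation with a size-dependent success
    criterion, and a synthetic-structure generator so the whole pipeline can
    be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
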