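Package: protonpath
Title: Proton Transfer Pathway Search and Group-Wise Conservation Analysis
    for Metalloenzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate proton transfer pathways (PTPs) in protein
    structures by a distance-cutoff relay search: starting from a buried
    cofactor anchor (for [FeFe] hydrogenases, the azadithiolate bridgehead
    amine of the H-cluster), chains of protonatable, hydroxyl-bearing or
    charged side chains are traced outward under a base heavy-atom distance
    cutoff with adaptive extension, until a solvent-exposed residue is
    reached. Surface exposure is decided by a deterministic Shrake-Rupley
    solvent accessible surface area calculation. Companion tools compute
    named atom-pair distances across structures, paired model-vs-model
    distance-difference statistics, and per-group multiple sequence
    alignment conservation profiles (consensus, information content,
    group-exclusive conservation calls) in a reference residue numbering.
    Seeded generators produce synthetic structures with planted relay
    chains and synthetic group alignments with planted conserved columns,
    providing ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
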