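Package: ultrastruct
Title: Structural Geometry Analysis of Ultra-High-Resolution Protein Crystals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the geometric analysis of ultra-high-resolution
    protein crystal structures, developed around the two-molecule insulin
    asymmetric unit: altloc- and occupancy-aware coordinate input/output,
    exact torsion and chirality geometry with internal-coordinate
    construction, disulphide-bridge conformer enumeration with chi3
    handedness, geometric hydrogen-bond detection with a water-network
    census and salt-bridge tables, rule-based secondary-structure
    assignment, crystallographic symmetry expansion for metal
    coordination spheres (rhombohedral space group 146 in the hexagonal
    setting), per-residue disorder ledgers with cross-chain and
    cross-structure correspondence, multi-model trajectory analysis, and
    deterministic synthetic-structure generators providing ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
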