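Package: helixhb
Title: Backbone Hydrogen-Bond Surveys and Helical Parameters for
    Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for surveying backbone hydrogen bonding in protein
    coordinate files.  Reads and writes PDB-format structures, places
    amide hydrogens from sp2 nitrogen geometry, detects backbone
    N-H...O=C hydrogen bonds with permissive geometric criteria
    (including three-centered, bifurcated bonds), assigns helices from
    i->i+3 / i->i+4 bond patterns, and aggregates resolution-binned
    survey tables, category reports and Ramachandran density /
    Boltzmann pseudo-energy maps.  Also provides closed-form relations
    between backbone torsions and helical parameters (residues per
    turn, rise per residue, pitch), a screw-axis fit by rigid
    superposition, a dipole-dipole interaction formula, and an
    internal-coordinate builder for ideal capped oligopeptide helices
    used as synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
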