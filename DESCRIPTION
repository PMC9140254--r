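Package: tunvar
Title: Evolutionary Variability of Protein Compartments and Active-Site Tunnels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the evolutionary variability of protein
    structural compartments and active-site tunnels. Curates homologous
    protein sequence sets (deduplication, catalytic-motif filtering, length
    screening), computes per-column Schneider entropy (normalized Shannon
    entropy) on a multiple sequence alignment, maps structure residues onto
    alignment columns, classifies compartments and tunnel linings as
    conserved or variable against a structure-trimmed background using the
    median-distance rule and the Epps-Singleton two-sample test, matches
    tunnels detected in crystal structures against tunnels detected in
    molecular-dynamics snapshots by occurrence thresholding and Jaccard
    distance over a dual-threshold grid, and builds entropy-versus-distance
    spatial profiles. Includes a seeded synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
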