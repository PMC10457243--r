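Package: plasmidnet
Title: Plasmidome Characterization: Iterons, Restriction Screens and
    Reciprocated Protein-Similarity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: In-silico characterization of small circular bacterial
    plasmids. Reads annotated replicons from GenBank flat files or FASTA
    with full circular-coordinate semantics, detects tandem iteron arrays
    in candidate replication origins and renders degenerate consensus
    strings, screens genetic modules for restriction-site availability
    for vector design, and builds reciprocated protein-similarity
    networks from all-vs-all gapped local alignments with Karlin-Altschul
    E-value filtering, including reference-based replicase (REP) and
    relaxase (MOB) family classification. A truth-tracked synthetic
    plasmid and protein-family generator makes every stage testable
    without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
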