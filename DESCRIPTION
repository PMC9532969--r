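Package: mitorecomb
Title: Repeat-Mediated Recombination Analysis for Circular Plant Mitogenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects maximal exact repeats in circular mitochondrial genomes,
    builds the reference and recombined local conformations for each repeat
    pair (repeat plus single-copy flanks), assigns paired-end short reads to
    conformations under alignment-length, junction-anchor and decoy filters,
    and estimates the per-repeat recombination frequency
    (Nab+Nba)/(Naa+Nbb+Nab+Nba) with a Wilson 95% interval. Includes circle
    decomposition of direct-repeat recombination into subgenomic circles,
    isomerisation by inverted repeats, and a seeded simulator of circular
    genomes with planted repeats and paired-end reads drawn from conformation
    mixtures, so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
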