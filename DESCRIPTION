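Package: ppstall
Title: Evolutionary Analysis of Polyproline Ribosome-Stalling Motifs in
    Bacterial Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and strength classification of polyproline
    ribosome-stalling motifs in protein sequences; enrichment and depletion
    statistics under composition-preserving shuffle nulls and a zero-order
    Markov word model; core/accessory pan-proteome comparison; maximum
    likelihood ancestral reconstruction of discrete stalling states on
    phylogenies with gain/loss event counting and the propensity of stalling
    effect change (PSEC) statistic; positional profiling relative to start
    sites, structural domains and transmembrane helices; translation
    efficiency correlation; and a synthetic-data generator that emulates all
    required inputs with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phytools,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
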