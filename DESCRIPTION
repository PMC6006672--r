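Package: tetransfer
Title: Detection of Horizontal Transposable Element Transfer Between Species
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Inference machinery for detecting horizontal exchange of
    transposable elements (TEs) between closely related species and for
    characterizing TE content. Implements Nei-Gojobori (1986) counting of
    synonymous and nonsynonymous divergence, Wright's effective number of
    codons, major-allele consensus building, classification of TE families
    as horizontally exchanged when their synonymous divergence falls below
    genic quantiles, an ENC-conditioned confirmation rule, neighbor-joining
    and Robinson-Foulds discordance checks, within-family polymorphism
    statistics (Tajima's D against a coalescent null, shared polymorphism,
    copy-number variability), a BLAST-hit decision tree for candidate TE
    classification with hit-count and relative-coverage filters, N-corrected
    sliding-window TE densities, and piRNA ping-pong signature detection
    (5' overlap spectrum and 1U/10A positional composition). A built-in
    simulator generates every input with known ground truth: TE families
    evolving on a species tree with and without injected transfers,
    coalescent-structured copy sets, coverage profiles, ping-pong-structured
    small-RNA reads, BLAST-style hit tables and genome mosaics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
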