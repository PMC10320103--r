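Package: chunkasm
Title: Targeted Diploid Assembly of Noisy Long Reads via Chunk Phasing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Haplotype-resolved assembly of a megabase-scale genomic region
    from noisy long reads (ONT-like, 5-10% error). Kilobase-scale chunks are
    sampled from the reads, aligned back to all reads at a relaxed identity
    threshold, and separated into their genomic copies by perturbing every
    possible single-base edit of a chunk under a pair hidden Markov model and
    stochastically clustering the reads on the edits that raise read
    likelihoods. The separated copies are serialized into a phased copy
    graph, homozygous stretches are resolved by read co-occurrence, and
    consensus sequences are polished by repeatedly applying positively
    supported perturbation edits. Includes a synthetic diploid genome and
    read simulator with truth ledgers, plus truth-based evaluation (contig
    counts, genome fraction, QV, Rand index, switch errors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
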