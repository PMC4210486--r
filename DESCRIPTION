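Package: atypicalr
Title: Detection of Atypical Genes in Virus Families with One-Class Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks coding sequences within a virus family from most atypical
    to most typical using compositional signatures (oligonucleotide, codon,
    amino-acid, position-specific nucleotide frequencies and GC content) and
    a one-class nu-SVM with a Gaussian kernel. Atypical genes are candidate
    recent horizontal gene transfers. Includes greedy redundancy reduction of
    input sequences, ranking-stability parameter selection via Spearman
    correlation sweeps over (nu, gamma), a GC-content baseline ranking,
    sliding-window segment ranking for single genomes, a synthetic
    coding-sequence generator with controlled compositional divergence, and a
    simulated-outlier injection benchmark evaluated by ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
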