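Package: mitocub
Title: Codon Usage Bias and Nucleotide Skew Analysis for Mitochondrial
    Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the thirteen mitochondrially encoded
    protein-coding genes of annotated vertebrate mitogenomes: CDS
    extraction with strand and incomplete-stop-codon handling, nucleotide
    composition and AT/GC skews, relative synonymous codon usage (RSCU)
    with codon-usage-pattern classification and codon aversion motifs,
    Wright's effective number of codons with the ENC-plot standard curve,
    and parity-rule-2 bias over four-fold degenerate codons. Includes a
    seeded synthetic mitogenome population generator with controllable
    codon bias, base composition and strand asymmetry, and an end-to-end
    pipeline producing plot-ready tables and a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
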