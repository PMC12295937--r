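Package: mitocub
Title: Codon Usage Bias Analysis for Mitochondrial Protein-Coding Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing codon usage bias in annotated mitochondrial
    genomes. Reads GenBank flat files and per-gene FASTA, extracts in-frame
    sense-strand coding sequences under any NCBI genetic code (handling
    light-strand genes and incomplete stop codons completed by 3' A residues),
    and computes the standard codon-usage diagnostics: relative synonymous
    codon usage (RSCU), Wright's effective number of codons (ENC) with the
    GC3s expected curve, parity-rule-2 bias plots, neutrality-plot regression
    of GC12 on GC3, and Pearson correlation matrices of composition
    parameters. Includes a synthetic coding-sequence generator with tunable
    GC mutation pressure and translational selection so that every stage of
    the pipeline, including the mutation-versus-selection diagnostics, can be
    validated against closed-form expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
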