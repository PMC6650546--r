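Package: codonaudit
Title: Codon-Level Audit of Transcription and Translation Optimization in Operons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects operons whose coding sequences are simultaneously
    optimized for cheap transcription (nucleotide and elemental economy of
    the transcript) and effective translation (efficiency, accuracy and
    protein synthesis cost). Implements relative synonymous codon usage
    (RSCU), the codon adaptation index (CAI) against genome-wide and
    ribosomal-protein references, Wright's effective number of codons (ENC),
    the tRNA adaptation index (tAI) with exact and wobble codon-anticodon
    pairing, codon-tRNA interaction networks with tRNA-access curves,
    abundance-weighted transcriptome ribonucleotide and elemental budgets
    with resampling nulls, and the supporting statistics (one-way PERMANOVA
    on codon-usage profiles, paired Wilcoxon, Welch t, chi-square of
    proportions, simple linear regression). A seeded synthetic-genome
    generator plants an operon with a methanotroph-like signature so the
    whole audit is testable end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
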