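Package: allopan
Title: Pangenome and Subgenome Divergence Analysis for Allopolyploid Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for gene-based pangenome analysis and subgenome divergence
    in allopolyploids: classification of orthogroup clusters into core,
    dispensable and private sets with pan/core saturation curves; detection of
    homeologous-exchange (HE) segments from windowed read-depth tracks;
    merging, filtering, lineage genotyping and cis-gene annotation of
    presence-absence variants (PAVs); homeolog expression bias testing with
    median-of-ratios normalization and FDR control; permutation tests for gene
    set overlap; and molecular-evolution utilities (Nei-Gojobori Ka/Ks, JC69
    divergence, LTR insertion ages, TE family-size contrasts). A synthetic
    data module generates every input with known ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    pROC,
    jsonlite
Config/testthat/edition: 3
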