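Package: gbmdyn
Title: Discovery and Characterization of Dynamic Gene Body Methylation from
    Read-Level CG Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying plant gene body methylation (GbM) states
    from per-cytosine bisulfite or enzymatic methyl-seq call tables. Pools
    symmetric CG dinucleotides, computes the per-CG read-level methylation
    heterogeneity fraction (the proportion of deduplicated reads, i.e. cells,
    that are methylated), classifies CG sites as unmethylated, heterogeneously
    methylated or fully methylated, calls CG differentially methylated regions
    between a wild-type and a demethylase-mutant methylome by aggregating
    differential CGs in overlapping 200-bp windows, and identifies Dynamic GbM
    genes (heterogeneously methylated in wild type, fully methylated in the
    eraser mutant) versus Stable GbM genes (binomial gene-body CG test with
    non-CG ceilings). Downstream modules test evolutionary conservation of the
    heterogeneous state in homologs against random gene sets, quantify
    chromatin enrichment (log2 fold enrichment over the genomic average,
    Cohen's d, chromatin-state overlap), and measure gene-expression
    plasticity (coefficient of variation, Fano factor, expression-decile
    dynamic range with an F-test, and the tissue-specificity inverse
    regression). A fully parameterized synthetic-data generator provides
    methylomes, ChIP tracks, homolog tables and expression matrices with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
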