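Package: fgmap
Title: Forward-Genetics Mapping-by-Sequencing of Recessive Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-backed toolkit for identifying the causal mutation of a
    monogenic recessive plant mutant from an F2 cross. Implements chi-square
    segregation testing against Mendelian ratios, cosegregation interval
    mapping from SNP-array genotypes of mutant-phenotype segregants,
    bulked-segregant SNP/Indel-index mapping with intra-cultivar background
    subtraction and depth/homozygosity filtering, variant effect prediction
    with frameshift re-translation (premature stop position and truncated
    protein length), and an RPKM-based two-group differential expression
    stage. A seeded synthetic-data module generates every input the pipeline
    consumes (reference, gene models, planted causal deletion, background
    variants, F2 meioses under the Haldane map, array genotypes, pooled
    allele counts, RNA-seq counts), so the whole chain can be validated
    end-to-end by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    vcfR
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
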