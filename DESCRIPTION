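Package: varconcord
Title: Transcript-Aware Variant Annotation and Annotation-Concordance Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Functional annotation of short genetic variants (SNVs and InDels)
    against transcript models, with two reporting conventions: a single
    most-severe consequence per variant under a fixed severity precedence, and
    all per-transcript consequences. Includes a consequence-term harmonization
    layer mapping fine-grained terms onto broad comparison categories,
    per-category concordance statistics between two annotation strategies,
    population-subset extraction from multi-sample VCFs with allele-count
    recomputation, summary statistics (SNV/InDel counts, Ts/Tv ratio, SNP
    density in fixed genomic bins), generic known-sites membership annotation,
    and a seeded synthetic-data generator that emulates population-scale
    variant call sets with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
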