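Package: priovar
Title: Rare-Disease Variant Prioritization with Pedigree Cosegregation
    and ACMG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements, as a tested and fully reproducible pipeline, the
    variant-prioritization analysis used to identify a causal homozygous
    frameshift duplication in a recessive connective-tissue disorder in a cat
    family: coding-consequence annotation with HGVS 3'-rule normalization, a
    case-versus-controls private-variant hard-filter cascade, autosomal
    recessive pedigree cosegregation, a minimal ACMG/AMP rule engine
    (PVS1/PM2/PP1), and wet-lab confirmation support (in-silico PCR and
    microsatellite parentage exclusion). A synthetic-cohort generator emulates
    the study family (one case, 77 control genomes, 20 candidate genes, a
    31-cat pedigree with 4 affected kittens) so the whole pipeline runs
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
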