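#!/usr/bin/env Rscript
# Stage 5 — ACMG-lite classification of the top candidate.
#
# Three evidence lines are computed from the pipeline's own outputs:
# PVS1 (null variant in a gene with an established loss-of-function
# mechanism), PM2 (mutant allele absent from the 77-genome control panel)
# and PP1 (perfect cosegregation with multiple affected family members),
# then combined with the consensus rules.
#
# Usage: Rscript analysis/05_classification.R

library(priovar)

genome <- read_fasta("results/cohort/reference.fa")
models <- read_gff3("results/cohort/genes.gff3")
ch <- read_vcf("results/cohort/cohort.vcf", genome = genome)
ped <- read_ped("results/cohort/pedigree.ped")
fam <- read_vcf("results/cohort/family.vcf", genome = genome)
lof_genes <- read_gene_list("results/cohort/lof_genes.txt")
top <- read.delim("results/top_variant.tsv")

case_id <- intersect(ch$samples, ped$id)
controls <- setdiff(ch$samples, case_id)

key <- paste(ch$variants$chrom, ch$variants$pos, ch$variants$ref,
             ch$variants$alt, sep = ":")
top_key <- paste(top$chrom, top$pos, top$ref, top$alt, sep = ":")
i <- match(top_key, key)
stopifnot(!is.na(i))

nv <- normalize_variant(top$chrom, top$pos, top$ref, top$alt, genome)
gene_of <- vapply(models, `[[`, "", "gene")
span_hit <- which(vapply(models, function(m) {
  sp <- c(min(m$cds$start), max(m$cds$end))
  top$pos >= sp[1] - 2 && top$pos <= sp[2] + 2
}, logical(1)))
cons <- call_consequence(nv, models[[span_hit[1]]], genome)

fam_key <- paste(fam$variants$chrom, fam$variants$pos, fam$variants$ref,
                 fam$variants$alt, sep = ":")
seg <- cosegregation_check(setNames(fam$gt[match(top_key, fam_key), ],
                                    fam$samples), ped)

ev <- list(evaluate_pvs1(cons, lof_genes),
           evaluate_pm2(ch, i, controls),
           evaluate_pp1(seg))
cls <- combine_evidence(ev)
print(cls)

jsonlite::write_json(list(
  variant = top_key, gene = cons$gene, category = cons$category,
  hgvs_c = cons$hgvs_c, hgvs_p = cons$hgvs_p,
  truncated_fraction = cons$truncated_fraction,
  evidence = lapply(ev, function(e) e[c("criterion", "strength", "triggered",
                                        "rationale")]),
  classification = cls$label, fired_rule = cls$fired_rule),
  "results/acmg.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/acmg.json\n")
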