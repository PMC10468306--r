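#!/usr/bin/env Rscript
# Stage 3 — the hard-filter cascade.
#
# Case-carried variants are filtered against the 77-control panel (private:
# every control homozygous reference or missing), then restricted to
# protein-changing consequences, then to the functional candidate genes,
# with heterozygous/homozygous counts (by case genotype) at every step.
# The case sample is identified as the one cohort sample that belongs to
# the pedigree.
#
# Usage: Rscript analysis/03_filter_cascade.R

library(priovar)

genome <- read_fasta("results/cohort/reference.fa")
ch <- read_vcf("results/cohort/cohort.vcf", genome = genome)
ann <- read.delim("results/annotations.tsv")
ped <- read_ped("results/cohort/pedigree.ped")
candidates <- read_gene_list("results/cohort/candidate_genes.txt")

case_id <- intersect(ch$samples, ped$id)
stopifnot(length(case_id) == 1)
controls <- setdiff(ch$samples, case_id)

casc <- filter_cascade(ch, ann, candidates, case_id, controls)
print(casc)
write_cascade(casc, "results/cascade.tsv")

for (part in c("het", "hom")) {
  surv <- surviving_variants(casc, 4, part)
  write.table(surv, sprintf("results/final_row_%s.tsv", part), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
top <- surviving_variants(casc, 4, "hom")
stopifnot(nrow(top) >= 1)
write.table(top[1, c("chrom", "pos", "ref", "alt")], "results/top_variant.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("top homozygous candidate: %s:%d %s>%s\n",
            top$chrom[1], top$pos[1], top$ref[1], top$alt[1]))
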