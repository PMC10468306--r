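#!/usr/bin/env Rscript
# Stage 6 — confirmation support.
#
# In-silico PCR with the designed genotyping assay sizes the wild-type and
# duplication alleles (the 1-bp duplication lengthens the product by one
# base, the discriminating signal of the fragment assay); the unrelated
# genotyping controls are tallied; and microsatellite parentage testing
# checks the sire against every affected kitten with the litter's dam.
#
# Usage: Rscript analysis/06_confirmation.R

library(priovar)

genome <- read_fasta("results/cohort/reference.fa")
ped <- read_ped("results/cohort/pedigree.ped")
primers <- read_primers("results/cohort/primers.tsv")
markers <- read_markers("results/cohort/markers.tsv")
gtc <- read_tsv_table("results/cohort/genotyping_controls.tsv",
                      required = c("sample", "genotype"))
top <- read.delim("results/top_variant.tsv")

pp <- primers[[1]]
amp_ref <- insilico_pcr(genome, pp)
mut <- apply_variant(genome, top$chrom, top$pos, top$ref, top$alt)
amp_mut <- insilico_pcr(mut, pp)
cat(sprintf("assay %s: %d bp (wild type) vs %d bp (mutant)\n", pp$name,
            amp_ref$length[1], amp_mut$length[1]))

ctrl_tab <- table(gt_class(gtc$genotype))
cat(sprintf("genotyping controls: %d cats, %d carrying the mutant allele\n",
            nrow(gtc), sum(gtc$genotype %in% c("0/1", "1/1"))))

affected <- ped$id[ped$affected == "affected"]
parentage <- lapply(affected, function(k) {
  r <- parentage_exclusion(markers, k, "SIRE", ped$dam[ped$id == k])
  print(r)
  list(offspring = k, compatible = r$compatible, loci_tested = r$loci_tested,
       excluded_loci = r$excluded_loci)
})

jsonlite::write_json(list(
  assay = pp$name,
  amplicon_reference_bp = amp_ref$length[1],
  amplicon_variant_bp = amp_mut$length[1],
  genotyping_controls = as.list(ctrl_tab),
  parentage = parentage),
  "results/confirmation.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/confirmation.json\n")
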