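#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study cohort.
#
# Emulates the sequenced family: one affected kitten sequenced as the case,
# 77 control genomes, 20 functional candidate genes (CAND01..CAND20) among
# 60 background genes on a single mini chromosome, a causal 1-bp duplication
# planted left-aligned inside a CDS poly-C run of CAND01, a heterozygous
# decoy missense in CAND02, a non-cosegregating decoy in CAND03, and the
# 31-cat pedigree (1 sire, 3 dams, 3 litters, 4 affected kittens) with a
# 16-locus microsatellite panel.
#
# Usage: Rscript analysis/01_simulate_cohort.R [seed]

library(priovar)

seed <- suppressWarnings(as.integer(commandArgs(trailingOnly = TRUE)[1]))
if (is.na(seed)) seed <- 1L
outdir <- "results/cohort"

cfg <- sim_config(seed = seed)
sim <- simulate_cohort(cfg, outdir = outdir)

cat(sprintf("wrote %s/: reference (%d bp), %d gene models, cohort VCF (%d records x %d samples)\n",
            outdir, nchar(sim$genome[["chr1"]]), length(sim$models),
            nrow(sim$cohort$variants), length(sim$cohort$samples)))
cat(sprintf("case sample: %s; causal dup planted at %s:%d (anchor-base form %s>%s)\n",
            sim$case_id, sim$truth$causal$chrom, sim$truth$causal$pos,
            sim$truth$causal$ref, sim$truth$causal$alt))
cat(sprintf("family: %d cats, %d affected; markers: %d loci\n",
            nrow(sim$ped), sum(sim$ped$affected == "affected"),
            length(unique(sim$markers$locus))))
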