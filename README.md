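# priovar

Rare-disease variant prioritization for a recessive Mendelian disorder in a
small family, built as a reproducible R package plus a numbered analysis
workflow. The motivating case is dermatosparaxis — the recessive
Ehlers–Danlos subtype caused by ADAMTS2 loss of function — in a cat family:
one affected kitten sequenced, a panel of control genomes, a candidate-gene
list, and a three-litter pedigree.

The package implements every stage of that analysis:

* **IO** for FASTA, VCF v4.2 (multi-allelic records split per alternate
  allele), GFF3 gene models, 6-column PED, marker/primer TSVs;
* **normalization** — parsimonious VCF left alignment *and* the HGVS
  3′-rule placement of the same edit, with duplication detection
  (`normalize_variant()`);
* **consequence annotation** by rebuilding and translating the mutant CDS,
  strand-aware, with HGVS `c.`/`p.` strings and the truncated fraction of
  the reading frame (`call_consequence()`);
* **the hard-filter cascade** — case-carried → private against all controls
  (`0/0` or `./.` required in every control) → protein-changing → candidate
  genes, with het/hom counts by case genotype (`filter_cascade()`);
* **cosegregation** under a fully penetrant autosomal recessive model, with
  obligate-carrier and Mendelian-transmission checks
  (`cosegregation_check()`);
* **ACMG-lite classification** — PVS1, PM2, PP1 evaluated from pipeline
  outputs and combined with the consensus rules (`combine_evidence()`);
* **confirmation** — exact-match in-silico PCR fragment sizing and
  microsatellite parentage exclusion (`insilico_pcr()`,
  `parentage_exclusion()`);
* a **synthetic-cohort generator** (`simulate_cohort()`) that emulates the
  study: 77 control genomes, 20 candidate genes, a causal homozygous 1-bp
  duplication planted left-aligned in a CDS poly-C run, decoy variants, a
  31-cat pedigree with 4 affected kittens, and a 16-locus marker panel —
  deterministic given a seed, with the planted truth returned for testing.

## Worked example

```r
library(priovar)
run <- run_all(sim_config(seed = 1))
print(run)
```

prints

```
== variant prioritization summary ==
Variant filtering in the case against 77 control genomes
 Filtering step                                                  Heterozygous Homozygous
 All variants carried by the case                                118          34
 Private variants                                                  2           1
 Protein-changing private variants                                 1           1
 Protein-changing private variants in functional candidate genes   1           1
top candidate: CAND01 frameshift c.698dup / p.(Ser235Glnfs*4) (80.5% of the ORF truncated)
cosegregation: perfect=TRUE (affected hom-alt 4, het 20, hom-ref 7)
ACMG: 3 evidence line(s) -> pathogenic
confirmation: CAND01-dup amplicon 169 bp (reference) vs 170 bp (variant)
parentage: sire compatible with 4/4 affected kittens
```

Reading the output: of the case's ~150 carried variants, exactly one
heterozygous (the planted decoy missense) and one homozygous variant (the
planted duplication) survive the full cascade. The homozygous survivor —
written left-aligned in the VCF at the 5′ end of the poly-C run — is
re-annotated under the HGVS 3′ rule as a duplication of the run's last
base, `c.698dup`, a frameshift `p.(Ser235Glnfs*4)` that truncates ~80% of
the 1213-aa protein. It cosegregates perfectly in the 31-cat family
(4 affected homozygotes / 20 carriers / 7 wild type), triggers PVS1 + PM2 +
PP1, and combines to *pathogenic*. The genotyping assay sizes the two
alleles 169 vs 170 bp, and the marker panel confirms the sire for all three
litters.

The same analysis is available as file-based stages:

```sh
Rscript analysis/01_simulate_cohort.R 1    # writes results/cohort/
Rscript analysis/02_annotate_variants.R    # results/annotations.tsv
Rscript analysis/03_filter_cascade.R       # results/cascade.tsv, top variant
Rscript analysis/04_segregation.R          # results/segregation.json
Rscript analysis/05_classification.R       # results/acmg.json
Rscript analysis/06_confirmation.R         # results/confirmation.json
Rscript analysis/07_full_pipeline.R 1      # results/summary.json
```

Each stage re-reads its inputs from `results/` through the package's IO
layer, so the workflow also exercises the file formats.

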