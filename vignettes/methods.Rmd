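---
title: "Methods: variant prioritization for a recessive disorder in a cat family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant prioritization for a recessive disorder in a cat family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priovar)
```

## The problem

A litter-clustered, fully penetrant skin-fragility phenotype in domestic
cats — dermatosparaxis, the recessive Ehlers–Danlos subtype caused by loss
of procollagen I N-proteinase (ADAMTS2) activity — is the motivating case
for this package. One affected kitten is whole-genome sequenced; the causal
variant must be recovered from millions of called variants using only a
control panel, a candidate-gene list, and the family. `priovar` implements
that prioritization end to end at desk scale: consequence annotation with
HGVS normalization, a private-variant hard-filter cascade, autosomal
recessive cosegregation, a minimal ACMG/AMP evidence engine, and the two
wet-lab confirmation computations (fragment-size genotyping by in-silico
PCR, microsatellite parentage exclusion).

Everything runs on a synthetic cohort whose generator is itself first-class,
tested code: the planted truth makes every downstream stage falsifiable.

## The filter cascade

The core statistic is a four-row count table over the case's variants,
partitioned by the case genotype (heterozygous / homozygous alternate):

1. all variants carried by the case;
2. *private* variants — every control is homozygous reference (`0/0`) or
   missing (`./.`); a missing control is explicitly non-contradicting, a
   missing case genotype excludes the variant;
3. protein-changing private variants — categories other than intergenic,
   intronic, synonymous (i.e. missense, frameshift, stop gain/loss, start
   loss, in-frame indels);
4. protein-changing private variants in the functional candidate genes
   (exact, case-insensitive symbol match).

Counts weakly decrease down both columns and the surviving sets are nested;
both properties are tested. Row 1 counts only case-carried sites (sites
where the case is `0/0` or `./.` never enter the cascade); whether a count
of *all* records is wanted instead is configurable (`row1 = "all"`), since
either convention is defensible for the first row. A variant overlapping
several genes survives row 4 if *any* overlapping gene is a candidate.

## Normalization and consequence annotation

An indel inside a repeat tract has many equivalent representations. Aligners
and VCFs use the leftmost (5'-most) placement; HGVS mandates the rightmost
(3'-most) placement in transcript orientation. `normalize_variant()` stores
both: the parsimonious left-aligned VCF form, and the 3'-shifted placement
obtained by rotating the inserted/deleted sequence rightwards while the next
reference base matches. An insertion whose inserted sequence equals the
reference immediately 5' of the shifted insertion point is flagged a
duplication. Both placements must edit the chromosome to the same string —
tested against a brute-force oracle that enumerates every equivalent
placement.

`call_consequence()` projects the edit into CDS coordinates (strand-aware;
transcripts are CDS-only, so `c.1` is the A of ATG), 3'-shifts again in
transcript orientation (for a minus-strand gene this is the opposite genomic
direction), rebuilds the mutant CDS, and translates both with the standard
genetic code. Classification is by protein comparison; a frameshifted frame
is allowed to read past the annotated stop into downstream genomic sequence
(up to 3 kb) when searching for the new stop. The frameshift protein
notation `p.(Xaa###Yaafs*N)` counts the stop codon itself in `N` (three
novel residues then a stop gives `fs*4`); an equivalent convention that
excludes the stop exists in the wild, and we deliberately follow the
stop-inclusive form only. Numerical/edge choices:

* variants spanning a CDS/intron boundary are reported as `unsupported`
  (kept visible and conservatively counted protein-changing), never dropped;
* splice-site effects are out of scope; edits within 2 bp of a CDS boundary
  carry a `near_splice` flag but are categorized by CDS overlap only;
* indels touching the start codon are `start_lost` regardless of frame,
  because the translation-comparison oracle is undefined there;
* a frame-preserving indel that still introduces a premature stop is
  `stop_gained`;
* the truncated fraction is `1 - mutant/wild-type` protein length,
  lengths excluding the stop codon, defined only for truncating categories.

## Cosegregation and Mendelian checks

Under the fully penetrant autosomal recessive model, perfect cosegregation
requires: every genotyped affected is `1/1`; no genotyped unaffected is
`1/1`; every genotyped obligate carrier (parent of an affected) is `0/1`
(ungenotyped parents are skipped, never imputed); and no parent–offspring
transmission is impossible. Individuals of unknown affection status are
exempt from the first two rules but still checked for transmission. A
missing genotype is unconstrained — it never creates a violation itself, but
it does not shield a contradiction visible from the genotyped side of a trio
(child `1/1` with a `0/0` sire is a violation even if the dam is
ungenotyped). No cosegregation likelihood is computed — the claim is only
perfect/not-perfect, with an informative-meiosis count reported
descriptively.

## ACMG-lite evidence

Three criteria are computed from pipeline outputs, at their canonical
strengths: PVS1 (very strong; frameshift/stop-gain/start-loss/stop-loss in a
gene whose loss-of-function disease mechanism is asserted via a
configuration list), PM2 (moderate; alternate allele count exactly zero
across the control panel, missing genotypes not counted as observations,
panel size at least 50 by default), PP1 (supporting; perfect cosegregation
with at least two genotyped affected homozygotes). The combining table
implements the full consensus pathogenic and likely-pathogenic rules over
the strength multiset, so externally asserted evidence can be mixed in;
benign criteria are not modeled — absence of benign evidence is assumed, a
documented limitation. The engine is a pure function of the evidence
multiset and is monotone: added evidence never downgrades the label (tested).

## The synthetic cohort: what it emulates, and what it does not

The generator's defaults are the study conditions, fixed once:

* 1 sequenced case, **77** control genomes, **48** unrelated genotyping
  controls, **20** candidate genes (`CAND01`–`CAND20`; the real candidate
  list is not public, so symbols are used), 60 background genes on one
  chromosome (~450 kb);
* the causal gene (`CAND01`) is engineered, not random: a 1213-aa protein
  whose CDS poly-C run (default length 6) ends at position 698, split over
  8 exons with the run in exon 4. Duplicating one C — emitted in the VCF
  left-aligned at the anchor base before the run, the way an alignment
  viewer shows it — annotates as `c.698dup`, `p.(Ser235Glnfs*4)`, and
  truncates 1 − 237/1213 ≈ 80% of the reading frame;
* a heterozygous decoy missense in `CAND02` private to the case (the
  COL1A2-like second survivor), and a non-cosegregating decoy in `CAND03`
  carried by controls and homozygous in unaffected family members (the
  variant a family-genotyping step excludes);
* the family: 1 sire, 3 dams, 3 litters of 9, 31 genotyped cats; founder
  carriers fixed, causal genotypes 4 affected `1/1` / 20 `0/1` / 7 `0/0`;
  affection is genotype-determined (no incomplete penetrance, as in the
  study family). Custom litter sizes switch to a true Mendelian gene drop;
* background variation: biallelic SNVs only (indel decoys would complicate
  the oracles without exercising new code), with control allele frequencies
  drawn from Beta(0.3, 3) — a rare-skewed site-frequency spectrum (mean
  0.09). Under that spectrum a background SNV survives the private filter
  homozygously with probability ≈ 5×10⁻⁶, so with 1000 background variants
  and candidate CDS ≈ 4% of the chromosome the planted duplication is
  essentially always the sole homozygous endpoint survivor; heterozygous
  background survivors occur at a low rate and are counted, not absorbed.
  Intergenic gaps of 2–6 kb keep most background variants noncoding, the
  dominant effect in the real protein-changing filter step;
* per-genotype missingness 0.02 for controls, never for the case;
* 16 microsatellite loci, 4–10 alleles each, founders from locus
  frequencies, offspring by Mendelian transmission (marker mutation is not
  modeled, so the exclusion threshold can stay at one locus);
* one genotyping assay designed around the run (unique 169-bp reference
  product; the duplication makes it 170 bp) and one around the decoy
  missense (152 bp).

Randomness is consumed in a documented stage order — reference (`seed`),
pedigree (`seed+1`), variants (`seed+2`), markers (`seed+3`) — so identical
config and seed give byte-identical artifacts (tested).

What passing tests therefore show: the machinery — normalization,
annotation, filtering, segregation, classification — is correct on data
whose truth is known by construction. What they do not show: performance on
real genomes, where sequencing artifacts, mapping error, structural
variants, population structure in the control panel, incomplete penetrance
and marker mutation all exist and are out of scope here.

## Problem sizes used by the checks

The bundled verification runs at sizes chosen to finish comfortably on one
CPU: 1,000 random indels against the placement-enumeration oracle; 1,000
planted CDS variants per strand against a translate-and-diff oracle built on
an independent translation codebase; a 500×78 genotype matrix against a
double-loop filter oracle; 50 generator seeds for endpoint recovery; the
exhaustive 27-case transmission table; and 1,000 marker-panel seeds for
parentage (true parents never excluded; an unrelated adult excluded at ≥1
locus in >99% of panels).

## Known limitations

One transcript per gene and first-overlap reporting; no UTR/regulatory
annotation; no splice-effect prediction; no frequency-database or
computational-predictor evidence (PM2 uses only the supplied panel); exact
primer matching only (no mismatch tolerance, no thermodynamics); no
parentage likelihood ratios; diploid autosomes only, unphased genotypes.
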