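# End-to-end orchestration: simulate -> annotate -> filter -> cosegregation
# -> classification -> confirmation, returning one machine-readable summary.
# Deterministic given the seed: two runs with the same config produce an
# identical summary object.

#' Run the whole prioritization pipeline on a synthetic cohort
#'
#' Generates (or accepts) the synthetic study cohort, annotates every
#' cohort variant, runs the four-step hard-filter cascade, takes the
#' homozygous survivor of the final row as the top candidate, checks
#' cosegregation in the family, evaluates and combines the ACMG evidence,
#' and computes the confirmation outputs (in-silico PCR product sizes on the
#' reference and the variant-applied haplotype; parentage exclusion of the
#' sire against every affected kitten).
#'
#' @param config A [sim_config()].
#' @param sim Optional pre-generated [simulate_cohort()] result (must match
#'   `config`); generated when `NULL`.
#' @param outdir Optional directory; when given, the cascade table and the
#'   summary JSON are written there.
#' @param quiet Suppress progress messages.
#' @return Object of class `pipeline_summary` (a nested list; see the
#'   `summary` element names).
#' @export
run_all <- function(config = sim_config(), sim = NULL, outdir = NULL,
                    quiet = FALSE) {
  say <- function(...) if (!quiet) message("[priovar] ", sprintf(...))
  if (is.null(sim)) {
    say("simulating cohort (seed %d)", config$seed)
    sim <- simulate_cohort(config)
  }
  if (sim$case_id %in% sim$control_ids) {
    stop("case id must not appear in the control panel")
  }

  say("annotating %d cohort variants", nrow(sim$cohort$variants))
  ann <- annotate_cohort(sim$cohort, sim$models, sim$genome)

  say("running the hard-filter cascade against %d controls",
      length(sim$control_ids))
  casc <- filter_cascade(sim$cohort, ann, sim$candidate_genes,
                         sim$case_id, sim$control_ids)
  hom_idx <- casc$surviving[[4]]$hom
  if (length(hom_idx) == 0) stop("no homozygous candidate survives the cascade")
  top_i <- hom_idx[1]
  top <- sim$cohort$variants[top_i, ]
  nv <- normalize_variant(top$chrom, top$pos, top$ref, top$alt, sim$genome)
  model <- sim$models[[which(vapply(sim$models, `[[`, "", "gene") ==
                               ann$gene[top_i])]]
  cons <- call_consequence(nv, model, sim$genome)

  say("top candidate: %s %s %s (%s)", cons$gene, cons$hgvs_c, cons$hgvs_p,
      cons$category)

  fam_key <- variant_key(sim$family$variants)
  fam_i <- match(variant_key(top), fam_key)
  if (is.na(fam_i)) stop("top candidate was not genotyped in the family")
  fam_gt <- stats::setNames(sim$family$gt[fam_i, ], sim$family$samples)
  seg <- cosegregation_check(fam_gt, sim$ped)

  ev <- list(evaluate_pvs1(cons, sim$lof_genes),
             evaluate_pm2(sim$cohort, top_i, sim$control_ids),
             evaluate_pp1(seg))
  cls <- combine_evidence(ev)
  say("classification: %s (%d evidence line(s) triggered)", cls$label,
      sum(vapply(ev, `[[`, TRUE, "triggered")))

  # confirmation: amplicon sizes on both haplotypes
  pp <- sim$primers[[1]]
  amp_ref <- insilico_pcr(sim$genome, pp)
  mut_genome <- apply_variant(sim$genome, top$chrom, top$pos, top$ref, top$alt)
  amp_mut <- insilico_pcr(mut_genome, pp)

  # parentage: sire vs every affected kitten, with the litter's dam
  affected <- sim$ped$id[sim$ped$affected == "affected"]
  parentage <- lapply(affected, function(k) {
    dam <- sim$ped$dam[sim$ped$id == k]
    parentage_exclusion(sim$markers, k, "SIRE", dam)
  })

  genotyping <- table(factor(gt_class(sim$genotyping_controls$genotype),
                             levels = c("hom_ref", "het", "hom_alt", "missing")))

  summary <- list(
    seed = config$seed,
    n_controls = length(sim$control_ids),
    cascade = casc$rows,
    top_variant = list(chrom = top$chrom, pos = top$pos, ref = top$ref,
                       alt = top$alt, gene = cons$gene,
                       category = cons$category, hgvs_genomic_pos = nv$hgvs_pos,
                       is_duplication = nv$is_duplication,
                       hgvs_c = cons$hgvs_c, hgvs_p = cons$hgvs_p,
                       truncated_fraction = cons$truncated_fraction),
    segregation = list(counts = as.list(seg$counts), perfect = seg$perfect,
                       n_violations = nrow(seg$violations),
                       n_meioses = seg$n_meioses),
    acmg = list(evidence = lapply(ev, function(e) {
                  e[c("criterion", "strength", "triggered", "rationale")]
                }),
                n_triggered = sum(vapply(ev, `[[`, TRUE, "triggered")),
                classification = cls$label, fired_rule = cls$fired_rule),
    confirmation = list(
      assay = pp$name,
      amplicon_reference_bp = if (nrow(amp_ref)) amp_ref$length[1] else NA_integer_,
      amplicon_variant_bp = if (nrow(amp_mut)) amp_mut$length[1] else NA_integer_,
      genotyping_controls = as.list(genotyping),
      parentage = lapply(parentage, function(p) {
        list(offspring = p$offspring, compatible = p$compatible,
             loci_tested = p$loci_tested,
             n_excluding = length(p$excluded_loci))
      })))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_cascade(casc, file.path(outdir, "cascade.tsv"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(summary = summary, cascade = casc, annotations = ann,
                 consequence = cons, segregation = seg, classification = cls,
                 sim = sim),
            class = "pipeline_summary")
}

#' @export
print.pipeline_summary <- function(x, ...) {
  s <- x$summary
  cat("== variant prioritization summary ==\n")
  print(x$cascade)
  cat(sprintf("top candidate: %s %s %s / %s (%.1f%% of the ORF truncated)\n",
              s$top_variant$gene, s$top_variant$category, s$top_variant$hgvs_c,
              s$top_variant$hgvs_p, 100 * s$top_variant$truncated_fraction))
  cat(sprintf("cosegregation: perfect=%s (affected hom-alt %d, het %d, hom-ref %d)\n",
              s$segregation$perfect, s$segregation$counts$hom_alt_affected,
              s$segregation$counts$het, s$segregation$counts$hom_ref))
  cat(sprintf("ACMG: %d evidence line(s) -> %s\n", s$acmg$n_triggered,
              s$acmg$classification))
  cat(sprintf("confirmation: %s amplicon %d bp (reference) vs %d bp (variant)\n",
              s$confirmation$assay, s$confirmation$amplicon_reference_bp,
              s$confirmation$amplicon_variant_bp))
  comp <- vapply(s$confirmation$parentage, `[[`, TRUE, "compatible")
  cat(sprintf("parentage: sire compatible with %d/%d affected kittens\n",
              sum(comp), length(comp)))
  invisible(x)
}
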