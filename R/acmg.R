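# A minimal ACMG/AMP rule engine: PVS1, PM2 and PP1 are evaluated from
# pipeline outputs; the combining rules accept the full criterion vocabulary
# so externally asserted evidence can be mixed in. Benign criteria are not
# modeled (documented limitation): absence of benign evidence is assumed.

ACMG_STRENGTHS <- c("very_strong", "strong", "moderate", "supporting")

default_strength <- function(criterion) {
  switch(criterion,
         PVS1 = "very_strong",
         PM2 = "moderate",
         PP1 = "supporting",
         stop("no default strength for criterion ", criterion))
}

#' Construct an ACMG evidence line
#'
#' @param criterion Criterion name (e.g. `"PVS1"`).
#' @param triggered Logical.
#' @param strength One of `very_strong`, `strong`, `moderate`, `supporting`;
#'   defaults to the criterion's canonical strength for PVS1/PM2/PP1.
#' @param rationale Free-text justification.
#' @return Object of class `acmg_evidence`.
#' @export
acmg_evidence <- function(criterion, triggered, strength = NULL, rationale = "") {
  strength <- strength %||% default_strength(criterion)
  stopifnot(strength %in% ACMG_STRENGTHS, is.logical(triggered))
  structure(list(criterion = criterion, strength = strength,
                 triggered = triggered, rationale = rationale),
            class = "acmg_evidence")
}

#' @export
print.acmg_evidence <- function(x, ...) {
  cat(sprintf("%s [%s] %s: %s\n", x$criterion, x$strength,
              if (x$triggered) "TRIGGERED" else "not triggered", x$rationale))
  invisible(x)
}

#' PVS1: null variant in a gene where loss of function is a known disease
#' mechanism
#'
#' @param consequence A [call_consequence()] result.
#' @param lof_genes Character vector of gene symbols with an established
#'   loss-of-function disease mechanism.
#' @return An [acmg_evidence()].
#' @export
evaluate_pvs1 <- function(consequence, lof_genes) {
  stopifnot(inherits(consequence, "consequence"))
  null_variant <- consequence$category %in%
    c("frameshift", "stop_gained", "start_lost", "stop_lost")
  lof <- !is.na(consequence$gene) &&
    toupper(consequence$gene) %in% toupper(lof_genes)
  acmg_evidence("PVS1", triggered = null_variant && lof,
                rationale = sprintf("category=%s; LOF-mechanism gene=%s",
                                    consequence$category, lof))
}

#' PM2: mutant allele absent from the control panel
#'
#' Absence means an alternate allele count of exactly zero over the control
#' genotypes, with missing genotypes not counted as observations; the panel
#' must reach a minimum size to count as informative.
#'
#' @param x A [cohort()].
#' @param variant_index Row index of the variant in the cohort.
#' @param control_ids Control sample ids.
#' @param min_controls Minimum number of controls for the criterion to be
#'   evaluable (default 50).
#' @return An [acmg_evidence()].
#' @export
evaluate_pm2 <- function(x, variant_index, control_ids, min_controls = 50L) {
  stopifnot(inherits(x, "cohort"))
  if (length(control_ids) == 0) {
    return(acmg_evidence("PM2", FALSE, rationale = "empty control panel"))
  }
  cls <- gt_class(x$gt[variant_index, control_ids])
  ac <- sum(cls == "het") + 2L * sum(cls == "hom_alt")
  ok_panel <- length(control_ids) >= min_controls
  acmg_evidence("PM2", triggered = ac == 0L && ok_panel,
                rationale = sprintf(
                  "alternate allele count %d across %d controls%s", ac,
                  length(control_ids),
                  if (!ok_panel) sprintf(" (insufficient, need >= %d)", min_controls)
                  else ""))
}

#' PP1: cosegregation with disease in multiple affected family members
#'
#' @param seg A [cosegregation_check()] result.
#' @param min_affected Minimum number of genotyped affected homozygotes for
#'   "multiple" (default 2).
#' @return An [acmg_evidence()].
#' @export
evaluate_pp1 <- function(seg, min_affected = 2L) {
  stopifnot(inherits(seg, "segregation_result"))
  n_aff <- unname(seg$counts["hom_alt_affected"] +
                    sum(seg$violations$rule == "affected_not_hom_alt"))
  n_aff_genotyped <- unname(seg$counts["hom_alt_affected"])
  acmg_evidence("PP1",
                triggered = isTRUE(seg$perfect) && n_aff_genotyped >= min_affected,
                rationale = sprintf("perfect=%s with %d genotyped affected",
                                    seg$perfect, n_aff_genotyped))
}

#' Combine ACMG evidence into a classification
#'
#' Implements the consensus combining rules for pathogenic and likely
#' pathogenic; anything else is of uncertain significance. Only triggered
#' evidence counts.
#'
#' @param evidence List of [acmg_evidence()] objects.
#' @return Object of class `acmg_classification`: `label` (`pathogenic`,
#'   `likely_pathogenic`, `uncertain_significance`), `fired_rule`,
#'   `evidence`.
#' @export
combine_evidence <- function(evidence) {
  stopifnot(all(vapply(evidence, inherits, logical(1), "acmg_evidence")))
  trig <- Filter(function(e) isTRUE(e$triggered), evidence)
  n <- table(factor(vapply(trig, function(e) e$strength, character(1)),
                    levels = ACMG_STRENGTHS))
  vs <- n[["very_strong"]]; s <- n[["strong"]]
  m <- n[["moderate"]]; p <- n[["supporting"]]

  rule <- NULL
  if (vs >= 1 && s >= 1) rule <- "pathogenic_1a"
  else if (vs >= 1 && m >= 2) rule <- "pathogenic_1b"
  else if (vs >= 1 && m == 1 && p >= 1) rule <- "pathogenic_1c"
  else if (vs >= 1 && p >= 2) rule <- "pathogenic_1d"
  else if (s >= 2) rule <- "pathogenic_2"
  else if (s == 1 && m >= 3) rule <- "pathogenic_3a"
  else if (s == 1 && m == 2 && p >= 2) rule <- "pathogenic_3b"
  else if (s == 1 && m == 1 && p >= 4) rule <- "pathogenic_3c"
  if (!is.null(rule)) label <- "pathogenic"
  else {
    if (vs >= 1 && m >= 1) rule <- "likely_pathogenic_1"
    else if (s == 1 && m >= 1 && m <= 2) rule <- "likely_pathogenic_2"
    else if (s == 1 && p >= 2) rule <- "likely_pathogenic_3"
    else if (m >= 3) rule <- "likely_pathogenic_4"
    else if (m == 2 && p >= 2) rule <- "likely_pathogenic_5"
    else if (m == 1 && p >= 4) rule <- "likely_pathogenic_6"
    label <- if (is.null(rule)) "uncertain_significance" else "likely_pathogenic"
  }
  structure(list(label = label, fired_rule = rule %||% "none",
                 evidence = evidence),
            class = "acmg_classification")
}

#' @export
print.acmg_classification <- function(x, ...) {
  cat("<acmg_classification>", x$label, sprintf("(rule %s)\n", x$fired_rule))
  for (e in x$evidence) print(e)
  invisible(x)
}
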