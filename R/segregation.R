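# Pedigree cosegregation under a fully penetrant autosomal recessive model:
# genotype-class tabulation by affection status, a perfect-cosegregation
# verdict with enumerated rule violations, and single-site Mendelian-error
# detection.

# possible transmitted alleles per genotype string (missing -> either allele)
transmissible <- function(gt) {
  switch(gt,
         "0/0" = 0L,
         "0/1" = c(0L, 1L), "1/0" = c(0L, 1L),
         "1/1" = 1L,
         "./." = c(0L, 1L),
         stop("unrecognized genotype string: ", gt))
}

gt_alleles <- function(gt) {
  switch(gt,
         "0/0" = c(0L, 0L),
         "0/1" = c(0L, 1L), "1/0" = c(0L, 1L),
         "1/1" = c(1L, 1L),
         "./." = NULL,
         stop("unrecognized genotype string: ", gt))
}

# is a child genotype transmissible from the two parental genotypes?
# missing genotypes never violate.
trio_consistent <- function(child, sire, dam) {
  ca <- gt_alleles(child)
  if (is.null(ca)) return(TRUE)
  s_opts <- transmissible(sire)
  d_opts <- transmissible(dam)
  for (s in s_opts) for (d in d_opts) {
    if (identical(sort(c(s, d)), sort(ca))) return(TRUE)
  }
  FALSE
}

#' Detect Mendelian errors at a single biallelic site
#'
#' Every individual with at least one genotyped parent is checked against the
#' diploid transmission table; an ungenotyped (or absent) parent constrains
#' nothing, so missing genotypes never violate.
#'
#' @param genotypes Named character vector of genotype strings (`0/0`, `0/1`,
#'   `1/1`, `./.`), names are pedigree ids; ungenotyped individuals may be
#'   omitted.
#' @param ped A [pedigree()].
#' @return Data frame of violations: `id`, `sire`, `dam`.
#' @export
mendelian_errors <- function(genotypes, ped) {
  stopifnot(inherits(ped, "pedigree"))
  unknown <- setdiff(names(genotypes), ped$id)
  if (length(unknown)) stop("genotype for unknown individual: ",
                            paste(unknown, collapse = ", "))
  gt_of <- function(id) {
    if (is.na(id) || !(id %in% names(genotypes))) "./." else genotypes[[id]]
  }
  bad <- list()
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (is.na(ped$sire[i]) && is.na(ped$dam[i])) next
    if (!trio_consistent(gt_of(id), gt_of(ped$sire[i]), gt_of(ped$dam[i]))) {
      bad[[length(bad) + 1L]] <- data.frame(id = id, sire = ped$sire[i],
                                            dam = ped$dam[i],
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(id = character(0), sire = character(0), dam = character(0))
}

#' Tabulate genotype classes by affection status
#'
#' @param genotypes Named character vector of genotype strings; names are
#'   pedigree ids.
#' @param ped A [pedigree()].
#' @return Named integer vector: `hom_alt_affected`, `hom_alt_unaffected`,
#'   `het`, `hom_ref`, `missing` (classes sum to the number of genotyped
#'   individuals).
#' @export
tabulate_segregation <- function(genotypes, ped) {
  stopifnot(inherits(ped, "pedigree"))
  unknown <- setdiff(names(genotypes), ped$id)
  if (length(unknown)) stop("genotype for unknown individual: ",
                            paste(unknown, collapse = ", "))
  cls <- gt_class(genotypes)
  aff <- ped$affected[match(names(genotypes), ped$id)]
  c(hom_alt_affected = sum(cls == "hom_alt" & aff == "affected"),
    hom_alt_unaffected = sum(cls == "hom_alt" & aff != "affected"),
    het = sum(cls == "het"),
    hom_ref = sum(cls == "hom_ref"),
    missing = sum(cls == "missing"))
}

#' Check cosegregation with an autosomal recessive phenotype
#'
#' Perfect cosegregation requires that (a) every genotyped affected
#' individual is homozygous alternate, (b) no genotyped unaffected individual
#' is, (c) every genotyped obligate carrier (parent of an affected) is
#' heterozygous, and (d) the site shows no parent-offspring Mendelian
#' inconsistency. Individuals of unknown affection status are exempt from
#' (a)/(b) but still checked for (d).
#'
#' @param genotypes Named character vector of genotype strings.
#' @param ped A [pedigree()].
#' @param model Inheritance model; only `"autosomal_recessive"` is supported.
#' @return Object of class `segregation_result`: `counts` (from
#'   [tabulate_segregation()]), `perfect`, `violations` (data frame `id`,
#'   `rule`), `obligate_carriers_checked`, `n_meioses` (informative count of
#'   parent-offspring transmissions with both sides genotyped).
#' @export
cosegregation_check <- function(genotypes, ped, model = "autosomal_recessive") {
  stopifnot(identical(model, "autosomal_recessive"), inherits(ped, "pedigree"))
  counts <- tabulate_segregation(genotypes, ped)
  cls <- stats::setNames(gt_class(genotypes), names(genotypes))
  aff <- stats::setNames(ped$affected, ped$id)
  viol <- list()
  add <- function(id, rule) {
    viol[[length(viol) + 1L]] <<- data.frame(id = id, rule = rule,
                                             stringsAsFactors = FALSE)
  }
  for (id in names(genotypes)) {
    if (cls[[id]] == "missing") next
    if (aff[[id]] == "affected" && cls[[id]] != "hom_alt") {
      add(id, "affected_not_hom_alt")
    }
    if (aff[[id]] == "unaffected" && cls[[id]] == "hom_alt") {
      add(id, "unaffected_hom_alt")
    }
  }
  affected_ids <- ped$id[ped$affected == "affected"]
  obligate <- unique(stats::na.omit(c(ped$sire[ped$id %in% affected_ids],
                                      ped$dam[ped$id %in% affected_ids])))
  checked <- character(0)
  for (id in obligate) {
    if (!(id %in% names(genotypes)) || cls[[id]] == "missing") next  # not imputed
    checked <- c(checked, id)
    if (cls[[id]] != "het") add(id, "obligate_carrier_not_het")
  }
  me <- mendelian_errors(genotypes, ped)
  for (id in me$id) add(id, "mendelian")
  violations <- if (length(viol)) do.call(rbind, viol)
    else data.frame(id = character(0), rule = character(0))
  genotyped <- names(genotypes)[cls[names(genotypes)] != "missing"]
  n_meioses <- sum(vapply(seq_len(nrow(ped)), function(i) {
    sum(c(ped$sire[i], ped$dam[i]) %in% genotyped) *
      as.integer(ped$id[i] %in% genotyped)
  }, integer(1)))
  structure(list(counts = counts, perfect = nrow(violations) == 0L,
                 violations = violations, obligate_carriers_checked = checked,
                 n_meioses = n_meioses, model = model),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat("<segregation_result> model:", x$model, "\n")
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  cat("  perfect:", x$perfect,
      sprintf("(%d violation(s), %d informative meioses)\n",
              nrow(x$violations), x$n_meioses))
  invisible(x)
}
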