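# The hard-filter cascade: case-carried variants, private against the
# control panel, protein-changing, candidate-gene prioritized, with per-step
# heterozygous/homozygous counts (partitioned by the CASE genotype).

#' Private-variant hard filter
#'
#' Keeps exactly the variants where the case sample is heterozygous or
#' homozygous alternate while every control is homozygous reference or
#' missing. A missing case genotype excludes the variant.
#'
#' @param x A [cohort()].
#' @param case_id Case sample id.
#' @param control_ids Character vector of control sample ids.
#' @return Logical vector over the cohort's variants (TRUE = survives).
#' @export
private_filter <- function(x, case_id, control_ids) {
  stopifnot(inherits(x, "cohort"))
  unknown <- setdiff(c(case_id, control_ids), x$samples)
  if (length(unknown)) stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  if (nrow(x$variants) == 0) return(logical(0))
  case_cls <- gt_class(x$gt[, case_id])
  keep <- case_cls %in% c("het", "hom_alt")
  if (length(control_ids)) {
    ctrl <- x$gt[, control_ids, drop = FALSE]
    ctrl_ok <- apply(ctrl, 1L, function(g) all(gt_class(g) %in% c("hom_ref", "missing")))
    keep <- keep & ctrl_ok
  }
  keep
}

#' Run the four-step hard-filter cascade
#'
#' Step 1: all variants carried by the case (case het or hom-alt), split by
#' the case genotype; step 2: private against the control panel; step 3:
#' protein-changing; step 4: in a candidate gene. Counts weakly decrease down
#' both columns.
#'
#' @param x A [cohort()].
#' @param annotations Annotation table from [annotate_cohort()], one row per
#'   cohort variant (same order).
#' @param candidate_genes Character vector of candidate gene symbols
#'   (matched case-insensitively).
#' @param case_id Case sample id.
#' @param control_ids Control sample ids.
#' @param row1 `"case-carried"` (default) restricts the first row to variants
#'   the case carries; `"all"` counts every record but still partitions by the
#'   case genotype (non-carried sites fall out of both columns either way).
#' @return Object of class `filter_cascade`: `rows` (label, het, hom),
#'   `surviving` (per-row list of het/hom variant index vectors) and
#'   `variants`.
#' @export
filter_cascade <- function(x, annotations, candidate_genes, case_id, control_ids,
                           row1 = c("case-carried", "all")) {
  row1 <- match.arg(row1)
  stopifnot(inherits(x, "cohort"), nrow(annotations) == nrow(x$variants))
  if (length(candidate_genes) == 0) {
    warning("empty candidate gene list; final cascade row will be 0/0")
  }
  case_cls <- if (nrow(x$variants)) gt_class(x$gt[, case_id]) else character(0)
  carried <- case_cls %in% c("het", "hom_alt")

  m1 <- carried  # the partition by case genotype empties non-carried sites anyway
  m2 <- m1 & private_filter(x, case_id, control_ids)
  m3 <- m2 & annotations$protein_changing %in% TRUE
  cand <- toupper(trimws(candidate_genes))
  in_cand <- !is.na(annotations$gene) & toupper(annotations$gene) %in% cand
  m4 <- m3 & in_cand

  masks <- list(m1, m2, m3, m4)
  labels <- c("All variants carried by the case",
              "Private variants",
              "Protein-changing private variants",
              "Protein-changing private variants in functional candidate genes")
  rows <- data.frame(label = labels, het = NA_integer_, hom = NA_integer_,
                     stringsAsFactors = FALSE)
  surviving <- vector("list", 4L)
  for (r in 1:4) {
    het_idx <- which(masks[[r]] & case_cls == "het")
    hom_idx <- which(masks[[r]] & case_cls == "hom_alt")
    rows$het[r] <- length(het_idx)
    rows$hom[r] <- length(hom_idx)
    surviving[[r]] <- list(het = het_idx, hom = hom_idx)
  }
  structure(list(rows = rows, surviving = surviving, variants = x$variants,
                 case_id = case_id, n_controls = length(control_ids)),
            class = "filter_cascade")
}

#' @export
print.filter_cascade <- function(x, ...) {
  cat(sprintf("Variant filtering in the case against %d control genomes\n",
              x$n_controls))
  df <- x$rows
  names(df) <- c("Filtering step", "Heterozygous", "Homozygous")
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Write a cascade count table as TSV
#'
#' @param cascade A [filter_cascade()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cascade <- function(cascade, path) {
  df <- cascade$rows
  names(df) <- c("filtering_step", "heterozygous", "homozygous")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Variants surviving a given cascade row
#'
#' @param cascade A [filter_cascade()].
#' @param row Row number (1-4).
#' @param partition `"het"`, `"hom"`, or `"both"`.
#' @return Data frame of surviving variant records.
#' @export
surviving_variants <- function(cascade, row = 4L, partition = c("both", "het", "hom")) {
  partition <- match.arg(partition)
  s <- cascade$surviving[[row]]
  idx <- switch(partition, het = s$het, hom = s$hom, both = sort(c(s$het, s$hom)))
  cls <- ifelse(idx %in% s$het, "het", "hom_alt")
  out <- cascade$variants[idx, , drop = FALSE]
  out$case_genotype_class <- cls
  rownames(out) <- NULL
  out
}
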