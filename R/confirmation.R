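# Wet-lab confirmation support: in-silico PCR amplicon prediction for
# genotyping assays (exact full-length primer matches only) and
# microsatellite parentage exclusion testing.

#' Construct a primer pair
#'
#' @param name Assay name.
#' @param forward,reverse Primer sequences 5'->3' (A/C/G/T only).
#' @param max_product Maximum product length reported (default 5000).
#' @return Object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, max_product = 5000L) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  stopifnot(nzchar(forward), nzchar(reverse),
            is_dna(forward, allow_n = FALSE), is_dna(reverse, allow_n = FALSE))
  structure(list(name = name, forward = forward, reverse = reverse,
                 max_product = as.integer(max_product)),
            class = "primer_pair")
}

#' Read a primer table (TSV: name, forward, reverse, max_product)
#'
#' @param path Path to the TSV file.
#' @return List of [primer_pair()] objects.
#' @export
read_primers <- function(path) {
  t <- read_tsv_table(path, required = c("name", "forward", "reverse"))
  mp <- if ("max_product" %in% names(t)) t$max_product else rep(5000L, nrow(t))
  lapply(seq_len(nrow(t)), function(i) {
    primer_pair(t$name[i], t$forward[i], t$reverse[i], mp[i])
  })
}

match_positions <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Predict PCR amplicons by exact primer matching
#'
#' Finds exact full-length matches of the forward primer with the
#' reverse-complemented reverse primer downstream of it (and the symmetric
#' opposite-strand orientation) and reports every pairing within
#' `max_product`. The amplicon length counts both primers.
#'
#' @param genome A [ref_genome()] (every sequence is searched), or a single
#'   DNA string.
#' @param pair A [primer_pair()].
#' @return Data frame: `chrom`, `start`, `end` (1-based, inclusive of both
#'   primers), `length`, `orientation` (`forward` = forward primer on the
#'   plus strand).
#' @export
insilico_pcr <- function(genome, pair) {
  stopifnot(inherits(pair, "primer_pair"))
  if (!inherits(genome, "ref_genome")) {
    genome <- ref_genome(c(seq = toupper(genome)))
  }
  out <- list()
  scan <- function(chrom, seq, p_left, p_right, orientation) {
    left <- match_positions(seq, p_left)
    right <- match_positions(seq, revcomp(p_right))
    for (i in left) for (j in right) {
      end <- j + nchar(p_right) - 1L
      len <- end - i + 1L
      if (j >= i + nchar(p_left) && len <= pair$max_product) {
        out[[length(out) + 1L]] <<- data.frame(
          chrom = chrom, start = i, end = end, length = len,
          orientation = orientation, stringsAsFactors = FALSE)
      }
    }
  }
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    scan(chrom, seq, pair$forward, pair$reverse, "forward")
    if (pair$forward != pair$reverse) {
      scan(chrom, seq, pair$reverse, pair$forward, "reverse")
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      orientation = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$end), , drop = FALSE]
}

# ---- microsatellite parentage ----------------------------------------------

#' Read a microsatellite genotype table
#'
#' Long-format TSV with columns `sample`, `locus`, `allele1`, `allele2`
#' (integer repeat lengths; NA for a missing locus).
#'
#' @param path Path to the TSV file.
#' @return Data frame of marker genotypes.
#' @export
read_markers <- function(path) {
  read_tsv_table(path, required = c("sample", "locus", "allele1", "allele2"))
}

marker_alleles <- function(markers, sample, locus) {
  row <- markers[markers$sample == sample & markers$locus == locus, , drop = FALSE]
  if (nrow(row) == 0) return(NULL)
  a <- c(row$allele1[1], row$allele2[1])
  if (anyNA(a)) NULL else as.integer(a)
}

#' Parentage exclusion test over a microsatellite panel
#'
#' A locus excludes a single candidate parent when the offspring shares no
#' allele with that parent; when both candidate parents are given, a locus
#' also excludes when no assignment of one offspring allele to each parent is
#' consistent. Loci with a missing genotype in any tested individual are
#' skipped and not counted.
#'
#' @param markers Marker table as from [read_markers()].
#' @param offspring_id,sire_id Offspring and candidate sire ids.
#' @param dam_id Optional candidate dam id for a trio test.
#' @return Object of class `parentage_result`: `offspring`, `parents`,
#'   `excluded_loci`, `compatible`, `loci_tested`.
#' @export
parentage_exclusion <- function(markers, offspring_id, sire_id, dam_id = NULL) {
  loci <- unique(markers$locus)
  if (length(loci) == 0) stop("empty marker panel")
  tested <- 0L
  excluded <- character(0)
  for (loc in loci) {
    o <- marker_alleles(markers, offspring_id, loc)
    s <- marker_alleles(markers, sire_id, loc)
    d <- if (is.null(dam_id)) NULL else marker_alleles(markers, dam_id, loc)
    if (is.null(o) || is.null(s) || (!is.null(dam_id) && is.null(d))) next
    tested <- tested + 1L
    ok <- if (is.null(dam_id)) {
      length(intersect(o, s)) > 0
    } else {
      # offspring alleles (o1, o2): one must come from each parent
      (o[1] %in% s && o[2] %in% d) || (o[2] %in% s && o[1] %in% d)
    }
    if (!ok) excluded <- c(excluded, loc)
  }
  if (tested == 0L) stop("no shared genotyped locus between ", offspring_id,
                         " and candidate parent(s)")
  structure(list(offspring = offspring_id,
                 parents = c(sire = sire_id, dam = dam_id %||% NA_character_),
                 excluded_loci = excluded,
                 compatible = length(excluded) == 0L,
                 loci_tested = tested),
            class = "parentage_result")
}

#' @export
print.parentage_result <- function(x, ...) {
  cat(sprintf("<parentage_result> %s vs %s: %s (%d/%d loci excluding)\n",
              x$offspring,
              paste(stats::na.omit(x$parents), collapse = " + "),
              if (x$compatible) "compatible" else "EXCLUDED",
              length(x$excluded_loci), x$loci_tested))
  invisible(x)
}
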