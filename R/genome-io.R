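# Readers/writers for every external format the pipeline touches, plus the
# in-memory data model (reference genome, variant cohort, gene models,
# pedigree). Coordinates are 1-based closed intervals throughout, the
# VCF/GFF3 convention.

# ---- reference genome -------------------------------------------------------

#' Construct a reference genome object
#'
#' @param sequences Named character vector, one uppercase DNA string per
#'   sequence (alphabet A/C/G/T/N).
#' @return An object of class `ref_genome` (named character vector).
#' @export
ref_genome <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("reference sequences must be named")
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate sequence name in reference: ",
         names(sequences)[duplicated(names(sequences))][1])
  }
  sequences <- toupper(sequences)
  bad <- !is_dna(sequences)
  if (any(bad)) {
    s <- sequences[bad][1]
    off <- regexpr("[^ACGTN]", s)
    stop(sprintf("non-ACGTN base in sequence '%s' at offset %d",
                 names(sequences)[bad][1], as.integer(off)))
  }
  structure(sequences, class = "ref_genome")
}

#' Read a FASTA file into a reference genome
#'
#' @param path Path to a FASTA file.
#' @return A [ref_genome()] with all sequences uppercased.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA header: ", nm[duplicated(nm)][1])
  }
  ref_genome(stats::setNames(toupper(as.character(ss)), nm))
}

#' Write a reference genome to FASTA (deterministic, 70-column wrap)
#'
#' @param genome A [ref_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

genome_base <- function(genome, chrom, pos) substr(genome[[chrom]], pos, pos)

genome_slice <- function(genome, chrom, start, end) {
  substr(genome[[chrom]], start, end)
}

# ---- genotypes --------------------------------------------------------------

#' Classify diploid genotype strings
#'
#' @param gt Character vector of unphased diploid genotype strings
#'   (`"0/0"`, `"0/1"`, `"1/0"`, `"1/1"`, `"./."`).
#' @return Character vector over `hom_ref`, `het`, `hom_alt`, `missing`.
#' @export
gt_class <- function(gt) {
  out <- rep(NA_character_, length(gt))
  out[gt == "0/0"] <- "hom_ref"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out[gt == "1/1"] <- "hom_alt"
  out[gt == "./."] <- "missing"
  if (anyNA(out)) stop("unrecognized genotype string: ", gt[is.na(out)][1])
  out
}

# ---- variant cohort ---------------------------------------------------------

#' Construct a variant cohort
#'
#' A cohort is a table of biallelic variant records plus a genotype matrix
#' (variants x samples) of unphased diploid calls.
#'
#' @param variants Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @param gt Character matrix, `nrow(variants)` rows, one column per sample,
#'   entries in `0/0`, `0/1`, `1/0`, `1/1`, `./.`.
#' @param genome Optional [ref_genome()]; if supplied, each `ref` is checked
#'   against the reference.
#' @return An object of class `cohort`: list with `variants`, `gt`, `samples`.
#' @export
cohort <- function(variants, gt, genome = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  variants <- data.frame(chrom = as.character(variants$chrom),
                         pos = as.integer(variants$pos),
                         ref = as.character(variants$ref),
                         alt = as.character(variants$alt),
                         stringsAsFactors = FALSE)
  gt <- as.matrix(gt)
  if (nrow(gt) != nrow(variants)) stop("gt rows must match variant rows")
  if (is.null(colnames(gt)) && ncol(gt) > 0) stop("gt columns must be named by sample")
  if (nrow(variants) > 0) {
    if (any(variants$pos < 1L)) stop("pos must be >= 1")
    if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt))) {
      stop("ref and alt must be non-empty")
    }
    if (any(variants$ref == variants$alt)) stop("ref must differ from alt")
    gt_class(as.vector(gt))  # validates entries
    if (!is.null(genome)) {
      for (i in seq_len(nrow(variants))) {
        seen <- genome_slice(genome, variants$chrom[i], variants$pos[i],
                             variants$pos[i] + nchar(variants$ref[i]) - 1L)
        if (!identical(seen, variants$ref[i])) {
          stop(sprintf("ref mismatch at %s:%d: VCF says %s, reference has %s",
                       variants$chrom[i], variants$pos[i], variants$ref[i], seen))
        }
      }
    }
  }
  structure(list(variants = variants, gt = gt, samples = colnames(gt)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d variants x %d samples\n",
              nrow(x$variants), length(x$samples)))
  invisible(x)
}

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

# recode one diploid GT string against alt allele k (1-based among the ALTs);
# any other alt allele counts as reference for privacy-filter purposes
recode_gt <- function(gt, k, n_alt) {
  if (gt %in% c(".", "./.", ".|.")) return("./.")
  if (grepl("|", gt, fixed = TRUE)) stop("phased genotype not supported: ", gt)
  parts <- strsplit(gt, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("non-diploid genotype call: ", gt)
  if (any(parts == ".")) return("./.")
  al <- suppressWarnings(as.integer(parts))
  if (anyNA(al)) stop("malformed genotype call: ", gt)
  if (any(al < 0L | al > n_alt)) stop("GT allele index out of range: ", gt)
  n <- sum(al == k)
  c("0/0", "0/1", "1/1")[n + 1L]
}

#' Read a VCF file into a cohort
#'
#' Multi-allelic records are split into one biallelic record per alternate
#' allele; genotypes are recoded against that allele (other alternate alleles
#' count as reference, the semantics the privacy filter needs). Records are
#' returned in file order, split records in ALT order.
#'
#' @param path Path to an uncompressed or gzipped VCF v4.2 file with GT in
#'   FORMAT.
#' @param genome Optional [ref_genome()] for REF validation.
#' @return A [cohort()].
#' @export
read_vcf <- function(path, genome = NULL) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_mat <- v@gt
  if (is.null(gt_mat) || ncol(gt_mat) < 2L) stop("VCF has no genotype columns")
  samples <- colnames(gt_mat)[-1L]
  out_var <- list(); out_gt <- list()
  for (i in seq_len(nrow(fix))) {
    fmt <- strsplit(gt_mat[i, 1L], ":", fixed = TRUE)[[1]]
    gti <- match("GT", fmt)
    if (is.na(gti)) stop("FORMAT without GT field at record ", i)
    calls <- vapply(gt_mat[i, -1L], function(s) {
      if (is.na(s)) return(".")
      strsplit(s, ":", fixed = TRUE)[[1]][gti]
    }, character(1), USE.NAMES = FALSE)
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      out_var[[length(out_var) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k], stringsAsFactors = FALSE)
      out_gt[[length(out_gt) + 1L]] <-
        vapply(calls, recode_gt, character(1), k = k, n_alt = length(alts),
               USE.NAMES = FALSE)
    }
  }
  variants <- do.call(rbind, out_var)
  gt <- do.call(rbind, out_gt)
  colnames(gt) <- samples
  cohort(variants, gt, genome = genome)
}

#' Write a cohort to a VCF v4.2 file
#'
#' Deterministic minimal serialization: GT-only FORMAT, `.` placeholders for
#' ID/QUAL/INFO, records in cohort order.
#'
#' @param x A [cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  body <- character(0)
  if (nrow(x$variants) > 0) {
    gt <- x$gt
    gt[gt == "1/0"] <- "0/1"
    body <- vapply(seq_len(nrow(x$variants)), function(i) {
      paste(c(x$variants$chrom[i], x$variants$pos[i], ".",
              x$variants$ref[i], x$variants$alt[i], ".", ".", ".", "GT",
              gt[i, ]), collapse = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- gene models ------------------------------------------------------------

#' Construct a gene model
#'
#' @param gene Gene symbol.
#' @param transcript Transcript identifier.
#' @param chrom Sequence name.
#' @param strand `"+"` or `"-"`.
#' @param cds_intervals Data frame with `start`, `end` (1-based closed),
#'   ordered 5'->3' in transcript order (descending genomic coordinates on
#'   the minus strand).
#' @param genome Optional [ref_genome()]; if supplied the encoded protein is
#'   validated (start codon, terminal stop, no internal stop) with a warning
#'   on failure.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene, transcript, chrom, strand, cds_intervals,
                       genome = NULL) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(cds_intervals),
            all(c("start", "end") %in% names(cds_intervals)))
  cds <- data.frame(start = as.integer(cds_intervals$start),
                    end = as.integer(cds_intervals$end))
  if (any(cds$end < cds$start)) stop("interval end before start in ", gene)
  g_ord <- cds[order(cds$start), , drop = FALSE]
  if (nrow(g_ord) > 1 && any(g_ord$start[-1] <= g_ord$end[-nrow(g_ord)])) {
    stop("overlapping CDS intervals in ", gene)
  }
  # enforce transcript order
  cds <- if (strand == "+") g_ord else g_ord[rev(seq_len(nrow(g_ord))), , drop = FALSE]
  rownames(cds) <- NULL
  total <- sum(cds$end - cds$start + 1L)
  if (total %% 3L != 0L) stop("CDS length of ", gene, " not divisible by 3")
  m <- structure(list(gene = gene, transcript = transcript, chrom = chrom,
                      strand = strand, cds = cds), class = "gene_model")
  if (!is.null(genome)) {
    p <- translate_dna(cds_sequence(m, genome))
    n <- nchar(p)
    if (substr(p, 1, 1) != "M" || substr(p, n, n) != "*" ||
        grepl("*", substr(p, 1, n - 1), fixed = TRUE)) {
      warning("gene model ", gene, " does not encode a clean ORF")
    }
  }
  m
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s%s, %d CDS segment(s), %d bp\n",
              x$gene, x$transcript, x$chrom, x$strand, nrow(x$cds),
              sum(x$cds$end - x$cds$start + 1L)))
  invisible(x)
}

#' Extract the coding sequence of a gene model
#'
#' Concatenates the CDS intervals in transcript order; on the minus strand
#' each genomic segment is reverse-complemented.
#'
#' @param model A [gene_model()].
#' @param genome A [ref_genome()].
#' @return The CDS as a single DNA string (starts with ATG for a valid model).
#' @export
cds_sequence <- function(model, genome) {
  chunks <- vapply(seq_len(nrow(model$cds)), function(i) {
    s <- genome_slice(genome, model$chrom, model$cds$start[i], model$cds$end[i])
    if (model$strand == "-") revcomp(s) else s
  }, character(1))
  paste(chunks, collapse = "")
}

gene_span <- function(model) c(min(model$cds$start), max(model$cds$end))

#' Read gene models from a GFF3 file
#'
#' Expects CDS features carrying `Parent` (transcript id) and `gene`
#' attributes, as written by [write_gff3()] (NCBI-style minimal annotation).
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional [ref_genome()] for ORF validation (warn-not-fail).
#' @return List of [gene_model()] objects, in file order of first appearance.
#' @export
read_gff3 <- function(path, genome = NULL) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0) return(list())
  parent <- vapply(as.list(cds$Parent), function(p) p[1], character(1))
  genes <- as.character(cds$gene)
  out <- list()
  for (tx in unique(parent)) {
    sel <- parent == tx
    iv <- data.frame(start = BiocGenerics::start(cds)[sel],
                     end = BiocGenerics::end(cds)[sel])
    strand <- as.character(BiocGenerics::strand(cds))[sel][1]
    out[[tx]] <- gene_model(gene = genes[sel][1], transcript = tx,
                            chrom = as.character(GenomicRanges::seqnames(cds))[sel][1],
                            strand = strand, cds_intervals = iv, genome = genome)
  }
  unname(out)
}

#' Write gene models to GFF3 (deterministic serialization)
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    sp <- gene_span(m)
    lines <- c(lines,
      sprintf("%s\tpriovar\tgene\t%d\t%d\t.\t%s\t.\tID=gene-%s;Name=%s",
              m$chrom, sp[1], sp[2], m$strand, m$gene, m$gene),
      sprintf("%s\tpriovar\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=gene-%s;gene=%s",
              m$chrom, sp[1], sp[2], m$strand, m$transcript, m$gene, m$gene))
    cds_g <- m$cds[order(m$cds$start), , drop = FALSE]
    # phase: number of bases to remove to reach the next codon start
    lens <- m$cds$end - m$cds$start + 1L
    phase_tx <- c(0L, cumsum(lens)[-length(lens)]) %% 3L
    phase_tx <- (3L - phase_tx) %% 3L
    ord <- order(m$cds$start)
    for (j in seq_len(nrow(cds_g))) {
      tx_idx <- ord[j]
      lines <- c(lines,
        sprintf("%s\tpriovar\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds-%s-%d;Parent=%s;gene=%s",
                m$chrom, cds_g$start[j], cds_g$end[j], m$strand,
                phase_tx[tx_idx], m$transcript, tx_idx, m$transcript, m$gene))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- pedigree ---------------------------------------------------------------

#' Construct a pedigree
#'
#' @param individuals Data frame with columns `id`, `sire`, `dam` (NA when
#'   unknown), `sex` (`male`/`female`/`unknown`), `affected`
#'   (`affected`/`unaffected`/`unknown`).
#' @return Object of class `pedigree` (validated data frame).
#' @export
pedigree <- function(individuals) {
  p <- data.frame(id = as.character(individuals$id),
                  sire = as.character(individuals$sire),
                  dam = as.character(individuals$dam),
                  sex = as.character(individuals$sex),
                  affected = as.character(individuals$affected),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(p$id)) stop("duplicate individual id: ",
                                p$id[duplicated(p$id)][1])
  stopifnot(all(p$sex %in% c("male", "female", "unknown")),
            all(p$affected %in% c("affected", "unaffected", "unknown")))
  for (col in c("sire", "dam")) {
    known <- !is.na(p[[col]])
    if (any(known & !(p[[col]] %in% p$id))) {
      stop("unresolved ", col, " id: ", p[[col]][known & !(p[[col]] %in% p$id)][1])
    }
  }
  # acyclicity by iterated founder-stripping (topological sort)
  remaining <- p$id
  parents <- stats::setNames(Map(function(s, d) c(s, d), p$sire, p$dam), p$id)
  repeat {
    founders <- remaining[vapply(remaining, function(id) {
      all(is.na(parents[[id]]) | !(parents[[id]] %in% remaining))
    }, logical(1))]
    if (length(founders) == 0) break
    remaining <- setdiff(remaining, founders)
  }
  if (length(remaining) > 0) stop("cyclic pedigree involving: ",
                                  paste(remaining, collapse = ", "))
  structure(p, class = c("pedigree", "data.frame"))
}

#' Read a 6-column PED file
#'
#' Columns: family, id, sire (0 = unknown), dam, sex (1 = male, 2 = female),
#' phenotype (2 = affected, 1 = unaffected, 0/-9 = unknown).
#'
#' @param path Path to the PED file.
#' @return A [pedigree()].
#' @export
read_ped <- function(path) {
  stopifnot(file.exists(path))
  t <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#",
                         col.names = c("fid", "id", "sire", "dam", "sex", "pheno"))
  pedigree(data.frame(
    id = as.character(t$id),
    sire = ifelse(t$sire == "0", NA_character_, as.character(t$sire)),
    dam = ifelse(t$dam == "0", NA_character_, as.character(t$dam)),
    sex = c("male", "female")[match(t$sex, c(1, 2))] |>
      (\(s) ifelse(is.na(s), "unknown", s))(),
    affected = c("unaffected", "affected")[match(t$pheno, c(1, 2))] |>
      (\(s) ifelse(is.na(s), "unknown", s))()))
}

#' Write a pedigree as a 6-column PED file
#'
#' @param ped A [pedigree()].
#' @param path Output path.
#' @param family Family identifier for column 1.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path, family = "FAM1") {
  sex <- match(ped$sex, c("male", "female"))
  sex[is.na(sex)] <- 0L
  pheno <- match(ped$affected, c("unaffected", "affected"))
  pheno[is.na(pheno)] <- 0L
  lines <- sprintf("%s\t%s\t%s\t%s\t%d\t%d", family, ped$id,
                   ifelse(is.na(ped$sire), "0", ped$sire),
                   ifelse(is.na(ped$dam), "0", ped$dam), sex, pheno)
  writeLines(lines, path)
  invisible(path)
}

# ---- plain tables -----------------------------------------------------------

#' Read a TSV table with '#' comments and a required schema
#'
#' @param path Path to the TSV file (header row required).
#' @param required Character vector of required column names.
#' @return A data frame.
#' @export
read_tsv_table <- function(path, required = character(0)) {
  stopifnot(file.exists(path))
  t <- utils::read.delim(path, header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE)
  missing <- setdiff(required, names(t))
  if (length(missing)) stop("missing required column(s): ",
                            paste(missing, collapse = ", "))
  t
}

#' Read a gene list (one symbol per line, '#' comments allowed)
#'
#' @param path Path to the list file.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  stopifnot(file.exists(path))
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}
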