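# Variant normalization: parsimony + left alignment (the VCF convention,
# what IGV displays) and 3'-shifting (the HGVS rule: an indel inside a repeat
# tract is reported at its most 3' equivalent placement). Both placements of
# the same edit are kept, because downstream consumers need both.

rotate_left <- function(s) {
  if (nchar(s) < 2L) return(s)
  paste0(substr(s, 2L, nchar(s)), substr(s, 1L, 1L))
}

# Reduce a (pos, ref, alt) record to parsimonious, left-aligned form against
# the chromosome sequence. Returns list(pos, ref, alt).
left_align <- function(seq, pos, ref, alt) {
  repeat {
    rl <- nchar(ref); al <- nchar(alt)
    if (rl > 0L && al > 0L &&
        substr(ref, rl, rl) == substr(alt, al, al) && !(rl == 1L && al == 1L)) {
      ref <- substr(ref, 1L, rl - 1L)
      alt <- substr(alt, 1L, al - 1L)
      if ((nchar(ref) == 0L || nchar(alt) == 0L)) {
        if (pos == 1L) {  # cannot extend left of the chromosome
          b <- ""
        } else {
          pos <- pos - 1L
          b <- substr(seq, pos, pos)
        }
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
        if (!nzchar(ref) || !nzchar(alt)) stop("cannot left-align at chromosome start")
      }
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

# Decompose a parsimonious anchor-base record into a pure edit:
# type "snv"  : replace seq[pos]
# type "mnv"  : replace seq[del_start..del_end] by ins (delins, no shifting)
# type "ins"  : insert `ins` after position `after`
# type "del"  : delete seq[del_start..del_end]
pure_edit <- function(pos, ref, alt) {
  rl <- nchar(ref); al <- nchar(alt)
  if (rl == 1L && al == 1L) {
    list(type = "snv", pos = pos, ref = ref, alt = alt)
  } else if (al > rl && substr(alt, 1L, rl) == ref) {
    list(type = "ins", after = pos + rl - 1L, ins = substr(alt, rl + 1L, al))
  } else if (rl > al && substr(ref, 1L, al) == alt) {
    list(type = "del", del_start = pos + al, del_end = pos + rl - 1L)
  } else {
    list(type = "mnv", del_start = pos, del_end = pos + rl - 1L, ins = alt)
  }
}

# Shift an insertion 3'-wards (rightwards) along `seq` to its most 3'
# equivalent placement. Returns list(after, ins).
shift3_ins <- function(seq, after, ins) {
  n <- nchar(seq)
  while (after < n && substr(seq, after + 1L, after + 1L) == substr(ins, 1L, 1L)) {
    ins <- rotate_left(ins)
    after <- after + 1L
  }
  list(after = after, ins = ins)
}

# Shift a deletion 3'-wards. Returns list(del_start, del_end, del = deleted seq).
shift3_del <- function(seq, del_start, del_end) {
  n <- nchar(seq)
  del <- substr(seq, del_start, del_end)
  while (del_end < n &&
         substr(seq, del_end + 1L, del_end + 1L) == substr(del, 1L, 1L)) {
    del <- rotate_left(del)
    del_start <- del_start + 1L
    del_end <- del_end + 1L
  }
  list(del_start = del_start, del_end = del_end, del = del)
}

#' Normalize a variant: VCF left alignment plus HGVS 3'-shifted placement
#'
#' The returned object carries both representations of the same edit: the
#' parsimonious left-aligned VCF form (`vcf`), and the most 3' genomic
#' placement (`hgvs_pos`) required by the HGVS 3'-rule. An insertion is
#' flagged as a duplication when, after 3'-shifting, the inserted sequence
#' equals the reference sequence immediately 5' of the insertion point.
#'
#' @param chrom,pos,ref,alt The variant in VCF representation (1-based).
#' @param genome A [ref_genome()]; `ref` must match it.
#' @return Object of class `normalized_variant`: list with `chrom`, `vcf`
#'   (pos/ref/alt), `edit` (the 3'-shifted pure edit), `hgvs_pos`,
#'   `is_duplication`, `type` (snv/ins/del/mnv).
#' @export
normalize_variant <- function(chrom, pos, ref, alt, genome) {
  seq <- genome[[chrom]]
  if (is.null(seq)) stop("unknown chromosome: ", chrom)
  pos <- as.integer(pos)
  seen <- substr(seq, pos, pos + nchar(ref) - 1L)
  if (!identical(seen, ref)) {
    stop(sprintf("ref mismatch at %s:%d: variant says %s, reference has %s",
                 chrom, pos, ref, seen))
  }
  if (ref == alt) stop("ref equals alt")
  la <- left_align(seq, pos, ref, alt)
  ed <- pure_edit(la$pos, la$ref, la$alt)
  is_dup <- FALSE
  if (ed$type == "snv") {
    hgvs_pos <- ed$pos
  } else if (ed$type == "ins") {
    sh <- shift3_ins(seq, ed$after, ed$ins)
    l <- nchar(sh$ins)
    is_dup <- sh$after >= l &&
      substr(seq, sh$after - l + 1L, sh$after) == sh$ins
    hgvs_pos <- sh$after
    ed <- list(type = "ins", after = sh$after, ins = sh$ins)
  } else if (ed$type == "del") {
    sh <- shift3_del(seq, ed$del_start, ed$del_end)
    hgvs_pos <- sh$del_start
    ed <- list(type = "del", del_start = sh$del_start, del_end = sh$del_end)
  } else {
    hgvs_pos <- ed$del_start
  }
  structure(list(chrom = chrom,
                 vcf = list(pos = la$pos, ref = la$ref, alt = la$alt),
                 edit = ed, hgvs_pos = hgvs_pos, is_duplication = is_dup,
                 type = ed$type),
            class = "normalized_variant")
}

#' @export
print.normalized_variant <- function(x, ...) {
  cat(sprintf("<normalized_variant> %s:%d %s>%s [%s%s], HGVS pos %d\n",
              x$chrom, x$vcf$pos, x$vcf$ref, x$vcf$alt, x$type,
              if (x$is_duplication) ", dup" else "", x$hgvs_pos))
  invisible(x)
}

#' Apply a variant to a reference genome
#'
#' Returns the edited chromosome set; the edited chromosome's length differs
#' from the reference by `nchar(alt) - nchar(ref)`.
#'
#' @param genome A [ref_genome()].
#' @param chrom,pos,ref,alt The variant in VCF representation.
#' @return A [ref_genome()] with the edit applied.
#' @export
apply_variant <- function(genome, chrom, pos, ref, alt) {
  seq <- genome[[chrom]]
  if (is.null(seq)) stop("unknown chromosome: ", chrom)
  pos <- as.integer(pos)
  seen <- substr(seq, pos, pos + nchar(ref) - 1L)
  if (!identical(seen, ref)) {
    stop(sprintf("ref mismatch at %s:%d: variant says %s, reference has %s",
                 chrom, pos, ref, seen))
  }
  out <- unclass(genome)
  out[[chrom]] <- paste0(substr(seq, 1L, pos - 1L), alt,
                         substr(seq, pos + nchar(ref), nchar(seq)))
  structure(out, class = "ref_genome")
}
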