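# Minimal coding-consequence annotator: project a normalized variant into
# transcript (CDS) coordinates, 3'-shift it in transcript orientation per the
# HGVS rule, rebuild and translate the mutant CDS, and classify the effect by
# comparing the two proteins. Transcripts are CDS-only (c.1 is the A of ATG).

# transcript-order cumulative offsets; cum[i] = CDS positions before interval i
cds_offsets <- function(model) {
  lens <- model$cds$end - model$cds$start + 1L
  c(0L, cumsum(lens))[seq_along(lens)]
}

# genomic position -> CDS position (NA when not in any CDS interval)
g2c <- function(model, p) {
  off <- cds_offsets(model)
  for (i in seq_len(nrow(model$cds))) {
    s <- model$cds$start[i]; e <- model$cds$end[i]
    if (p >= s && p <= e) {
      return(if (model$strand == "+") off[i] + (p - s + 1L) else off[i] + (e - p + 1L))
    }
  }
  NA_integer_
}

# interval index containing genomic position p, or NA
interval_of <- function(model, p) {
  hit <- which(p >= model$cds$start & p <= model$cds$end)
  if (length(hit)) hit[1] else NA_integer_
}

# Project a pure genomic edit into CDS space. Returns a list:
#   snv: list(type, cpos, ref, alt)           (transcript-strand bases)
#   ins: list(type, after, ins)               (insert after CDS pos `after`)
#   del: list(type, start, end)               (CDS segment deleted)
#   mnv: list(type, start, end, ins)
# or the string "outside" (no CDS overlap), or an error for boundary-spanning.
project_edit <- function(model, edit) {
  minus <- model$strand == "-"
  if (edit$type == "snv") {
    c1 <- g2c(model, edit$pos)
    if (is.na(c1)) return("outside")
    ref <- edit$ref; alt <- edit$alt
    if (minus) { ref <- revcomp(ref); alt <- revcomp(alt) }
    return(list(type = "snv", cpos = c1, ref = ref, alt = alt))
  }
  if (edit$type == "ins") {
    i1 <- interval_of(model, edit$after)
    i2 <- interval_of(model, edit$after + 1L)
    if (is.na(i1) && is.na(i2)) return("outside")
    if (is.na(i1) || is.na(i2) || i1 != i2) {
      stop("unsupported variant: insertion at a CDS/intron boundary of ", model$gene)
    }
    if (minus) {
      return(list(type = "ins", after = g2c(model, edit$after + 1L),
                  ins = revcomp(edit$ins)))
    }
    return(list(type = "ins", after = g2c(model, edit$after), ins = edit$ins))
  }
  # del / mnv: genomic segment del_start..del_end
  i1 <- interval_of(model, edit$del_start)
  i2 <- interval_of(model, edit$del_end)
  if (is.na(i1) && is.na(i2)) {
    # fully outside only if no interval is contained inside the span either
    inside <- any(model$cds$start >= edit$del_start & model$cds$end <= edit$del_end)
    if (!inside) return("outside")
    stop("unsupported variant: deletion spans a CDS/intron boundary of ", model$gene)
  }
  if (is.na(i1) || is.na(i2) || i1 != i2) {
    stop("unsupported variant: deletion spans a CDS/intron boundary of ", model$gene)
  }
  a <- g2c(model, edit$del_start); b <- g2c(model, edit$del_end)
  res <- list(type = edit$type, start = min(a, b), end = max(a, b))
  if (edit$type == "mnv") res$ins <- if (minus) revcomp(edit$ins) else edit$ins
  res
}

# 3'-shift a projected edit along the CDS sequence (transcript orientation)
shift3_cds <- function(cds_seq, pe) {
  if (pe$type == "ins") {
    sh <- shift3_ins(cds_seq, pe$after, pe$ins)
    list(type = "ins", after = sh$after, ins = sh$ins)
  } else if (pe$type == "del") {
    sh <- shift3_del(cds_seq, pe$start, pe$end)
    list(type = "del", start = sh$del_start, end = sh$del_end)
  } else pe
}

# apply a projected edit to the CDS string
apply_cds_edit <- function(cds_seq, pe) {
  n <- nchar(cds_seq)
  switch(pe$type,
    snv = paste0(substr(cds_seq, 1L, pe$cpos - 1L), pe$alt,
                 substr(cds_seq, pe$cpos + 1L, n)),
    ins = paste0(substr(cds_seq, 1L, pe$after), pe$ins,
                 substr(cds_seq, pe$after + 1L, n)),
    del = paste0(substr(cds_seq, 1L, pe$start - 1L),
                 substr(cds_seq, pe$end + 1L, n)),
    mnv = paste0(substr(cds_seq, 1L, pe$start - 1L), pe$ins,
                 substr(cds_seq, pe$end + 1L, n)))
}

# genomic sequence downstream of the stop codon in transcript orientation,
# used so a frameshifted ORF can run past the annotated stop
downstream_seq <- function(model, genome, n = 3000L) {
  chrom_len <- nchar(genome[[model$chrom]])
  if (model$strand == "+") {
    s <- max(model$cds$end) + 1L
    if (s > chrom_len) return("")
    genome_slice(genome, model$chrom, s, min(chrom_len, s + n - 1L))
  } else {
    e <- min(model$cds$start) - 1L
    if (e < 1L) return("")
    revcomp(genome_slice(genome, model$chrom, max(1L, e - n + 1L), e))
  }
}

hgvs_c_string <- function(pe, is_dup_cds) {
  switch(pe$type,
    snv = sprintf("c.%d%s>%s", pe$cpos, pe$ref, pe$alt),
    ins = {
      l <- nchar(pe$ins)
      if (is_dup_cds) {
        if (l == 1L) sprintf("c.%ddup", pe$after)
        else sprintf("c.%d_%ddup", pe$after - l + 1L, pe$after)
      } else sprintf("c.%d_%dins%s", pe$after, pe$after + 1L, pe$ins)
    },
    del = if (pe$start == pe$end) sprintf("c.%ddel", pe$start)
          else sprintf("c.%d_%ddel", pe$start, pe$end),
    mnv = sprintf("c.%d_%ddelins%s", pe$start, pe$end, pe$ins))
}

# first index at which two protein strings differ (NA if one is a prefix)
first_diff <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n > 0) {
    va <- utf8ToInt(substr(a, 1, n)); vb <- utf8ToInt(substr(b, 1, n))
    d <- which(va != vb)
    if (length(d)) return(d[1])
  }
  if (nchar(a) == nchar(b)) NA_integer_ else n + 1L
}

#' Predict the coding consequence of a normalized variant on a gene model
#'
#' The mutant CDS is rebuilt in transcript coordinates (strand-aware,
#' 3'-shifted per the HGVS rule), both CDS are translated, and the proteins
#' compared. A frameshifted open reading frame is allowed to run past the
#' annotated stop into downstream genomic sequence when searching for the new
#' stop codon.
#'
#' @param nv A [normalize_variant()] result.
#' @param model A [gene_model()] on the same chromosome.
#' @param genome A [ref_genome()].
#' @return Object of class `consequence`: gene, transcript, category
#'   (intergenic/intronic/synonymous/missense/inframe_insertion/
#'   inframe_deletion/frameshift/stop_gained/stop_lost/start_lost), `hgvs_c`,
#'   `hgvs_p`, `truncated_fraction` (NA unless a premature stop shortens the
#'   protein), `protein_changing`, `near_splice`.
#' @export
call_consequence <- function(nv, model, genome) {
  stopifnot(inherits(nv, "normalized_variant"))
  mk <- function(category, hgvs_c = NA_character_, hgvs_p = NA_character_,
                 trunc = NA_real_, near_splice = FALSE,
                 wt_len = NA_integer_, mut_len = NA_integer_) {
    structure(list(gene = model$gene, transcript = model$transcript,
                   category = category, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
                   truncated_fraction = trunc,
                   protein_changing = !(category %in%
                     c("intergenic", "intronic", "synonymous")),
                   near_splice = near_splice,
                   wt_len = wt_len, mut_len = mut_len),
              class = "consequence")
  }
  sp <- gene_span(model)
  edit <- nv$edit
  span <- switch(edit$type,
                 snv = c(edit$pos, edit$pos),
                 ins = c(edit$after, edit$after + 1L),
                 del = c(edit$del_start, edit$del_end),
                 mnv = c(edit$del_start, edit$del_end))
  if (!identical(nv$chrom, model$chrom) || span[2] < sp[1] || span[1] > sp[2]) {
    out <- mk("intergenic")
    out$gene <- NA_character_; out$transcript <- NA_character_
    return(out)
  }
  bounds <- c(model$cds$start, model$cds$end)
  near <- min(abs(c(outer(span, bounds, "-")))) <= 2L

  pe <- project_edit(model, edit)
  if (identical(pe, "outside")) return(mk("intronic", near_splice = near))

  cds <- cds_sequence(model, genome)
  pe <- shift3_cds(cds, pe)
  is_dup_cds <- FALSE
  if (pe$type == "ins") {
    l <- nchar(pe$ins)
    is_dup_cds <- pe$after >= l && substr(cds, pe$after - l + 1L, pe$after) == pe$ins
  }
  hgvs_c <- hgvs_c_string(pe, is_dup_cds)

  mut_cds <- apply_cds_edit(cds, pe)
  wt_prot_full <- translate_dna(cds)
  wt_stop <- regexpr("*", wt_prot_full, fixed = TRUE)
  wt_prot <- if (wt_stop > 0) substr(wt_prot_full, 1L, wt_stop - 1L) else wt_prot_full
  wt_len <- nchar(wt_prot)

  mut_trans_full <- translate_dna(paste0(mut_cds, downstream_seq(model, genome)))
  mut_stop <- regexpr("*", mut_trans_full, fixed = TRUE)
  has_stop <- mut_stop > 0
  mut_prot <- if (has_stop) substr(mut_trans_full, 1L, mut_stop - 1L) else mut_trans_full
  mut_len <- nchar(mut_prot)

  trunc <- if (has_stop && mut_len < wt_len) 1 - mut_len / wt_len else NA_real_

  touches_start <- switch(pe$type,
                          snv = pe$cpos <= 3L,
                          ins = pe$after < 3L,
                          del = pe$start <= 3L,
                          mnv = pe$start <= 3L)
  delta <- switch(pe$type,
                  snv = 0L, ins = nchar(pe$ins),
                  del = -(pe$end - pe$start + 1L),
                  mnv = nchar(pe$ins) - (pe$end - pe$start + 1L))

  if (pe$type != "snv" && touches_start) {
    return(mk("start_lost", hgvs_c, "p.(Met1?)", near_splice = near,
              wt_len = wt_len, mut_len = mut_len))
  }
  if (pe$type == "snv" && pe$cpos <= 3L && substr(mut_prot, 1L, 1L) != "M") {
    return(mk("start_lost", hgvs_c, "p.(Met1?)", near_splice = near,
              wt_len = wt_len, mut_len = mut_len))
  }

  if (delta %% 3L != 0L) {
    i <- first_diff(paste0(wt_prot, "*"),
                    paste0(mut_prot, if (has_stop) "*" else ""))
    if (is.na(i)) i <- wt_len + 1L
    wt_aa <- if (i <= wt_len) aa3_at(wt_prot, i) else "*"
    mut_aa <- if (i <= mut_len) aa3_at(mut_prot, i) else "*"
    hgvs_p <- if (mut_aa == "*") {
      sprintf("p.(%s%d*)", wt_aa, i)
    } else if (has_stop) {
      sprintf("p.(%s%d%sfs*%d)", wt_aa, i, mut_aa, mut_len - i + 2L)
    } else {
      sprintf("p.(%s%d%sfs*?)", wt_aa, i, mut_aa)
    }
    return(mk("frameshift", hgvs_c, hgvs_p, trunc, near,
              wt_len = wt_len, mut_len = mut_len))
  }

  # frame-preserving from here on
  if (identical(wt_prot, mut_prot) && has_stop && mut_len == wt_len) {
    i <- ceiling(switch(pe$type, snv = pe$cpos, ins = pe$after,
                        pe$start) / 3)
    lab <- if (i <= wt_len) aa3_at(wt_prot, i) else "*"
    return(mk("synonymous", hgvs_c, sprintf("p.(%s%d=)", lab, i),
              near_splice = near, wt_len = wt_len, mut_len = mut_len))
  }
  if (!has_stop || mut_len > wt_len) {
    # annotated stop destroyed and read-through extends the protein
    ext <- if (has_stop) sprintf("ext*%d", mut_len - wt_len) else "ext*?"
    new_aa <- if (mut_len >= wt_len + 1L) aa3_at(mut_prot, wt_len + 1L) else "Xaa"
    return(mk("stop_lost", hgvs_c, sprintf("p.(*%d%s%s)", wt_len + 1L, new_aa, ext),
              near_splice = near, wt_len = wt_len, mut_len = mut_len))
  }
  if (mut_len < wt_len && pe$type == "snv") {
    i <- first_diff(wt_prot, mut_prot)
    i <- if (is.na(i)) mut_len + 1L else i
    return(mk("stop_gained", hgvs_c, sprintf("p.(%s%d*)", aa3_at(wt_prot, i), i),
              trunc, near, wt_len = wt_len, mut_len = mut_len))
  }
  if (pe$type == "snv") {
    i <- first_diff(wt_prot, mut_prot)
    return(mk("missense", hgvs_c,
              sprintf("p.(%s%d%s)", aa3_at(wt_prot, i), i, aa3_at(mut_prot, i)),
              near_splice = near, wt_len = wt_len, mut_len = mut_len))
  }
  # in-frame indel / delins: a mutant protein shorter than the wild type
  # length adjusted for the indel means a premature stop was introduced
  if (has_stop && mut_len < wt_len + delta %/% 3L) {
    i <- first_diff(wt_prot, mut_prot)
    i <- if (is.na(i)) mut_len + 1L else i
    lab <- if (i <= wt_len) aa3_at(wt_prot, i) else "*"
    return(mk("stop_gained", hgvs_c, sprintf("p.(%s%d*)", lab, i),
              trunc, near, wt_len = wt_len, mut_len = mut_len))
  }
  cat_lab <- if (delta > 0L) "inframe_insertion" else "inframe_deletion"
  i <- first_diff(wt_prot, mut_prot)
  i <- if (is.na(i)) min(wt_len, mut_len) + 1L else i
  hgvs_p <- if (delta < 0L) {
    ndel <- -delta / 3L
    if (ndel == 1L) sprintf("p.(%s%ddel)", aa3_at(wt_prot, i), i)
    else sprintf("p.(%s%d_%s%ddel)", aa3_at(wt_prot, i), i,
                 aa3_at(wt_prot, i + ndel - 1L), i + ndel - 1L)
  } else {
    nins <- delta / 3L
    ins_aa <- paste(aa3(substr(mut_prot, i, i + nins - 1L)), collapse = "")
    sprintf("p.(%s%d_%s%dins%s)", aa3_at(wt_prot, max(i - 1L, 1L)), max(i - 1L, 1L),
            aa3_at(wt_prot, i), i, ins_aa)
  }
  mk(cat_lab, hgvs_c, hgvs_p, near_splice = near,
     wt_len = wt_len, mut_len = mut_len)
}

#' @export
print.consequence <- function(x, ...) {
  cat(sprintf("<consequence> %s (%s): %s %s %s\n",
              x$gene %||% "-", x$transcript %||% "-", x$category,
              x$hgvs_c %||% "", x$hgvs_p %||% ""))
  invisible(x)
}

#' Fraction of the wild-type open reading frame removed by a truncation
#'
#' `1 - mutant length / wild-type length`, protein lengths excluding the stop
#' codon.
#'
#' @param consequence A [call_consequence()] result with category
#'   `frameshift` or `stop_gained`.
#' @return Numeric in `[0, 1]`.
#' @export
truncation_fraction <- function(consequence) {
  stopifnot(inherits(consequence, "consequence"))
  if (!consequence$category %in% c("frameshift", "stop_gained")) {
    stop("truncation_fraction is defined only for truncating consequences, got ",
         consequence$category)
  }
  consequence$truncated_fraction
}

#' Annotate every variant of a cohort against a set of gene models
#'
#' Each variant is normalized and annotated against the first gene model
#' whose genomic span it overlaps (the annotator reports one transcript per
#' variant). Boundary-spanning edits are reported with category
#' `unsupported`, never dropped.
#'
#' @param x A [cohort()].
#' @param models List of [gene_model()] objects.
#' @param genome A [ref_genome()].
#' @return Data frame with one row per variant: `chrom`, `pos_vcf`,
#'   `pos_hgvs`, `ref`, `alt`, `gene`, `category`, `hgvs_c`, `hgvs_p`,
#'   `truncated_fraction`, `protein_changing`, `near_splice`.
#' @export
annotate_cohort <- function(x, models, genome) {
  stopifnot(inherits(x, "cohort"))
  n <- nrow(x$variants)
  spans <- do.call(rbind, lapply(models, function(m) {
    sp <- gene_span(m)
    data.frame(chrom = m$chrom, start = sp[1], end = sp[2])
  }))
  out <- data.frame(chrom = x$variants$chrom, pos_vcf = NA_integer_,
                    pos_hgvs = NA_integer_, ref = x$variants$ref,
                    alt = x$variants$alt, gene = NA_character_,
                    category = "intergenic", hgvs_c = NA_character_,
                    hgvs_p = NA_character_, truncated_fraction = NA_real_,
                    protein_changing = FALSE, near_splice = FALSE,
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  hits <- rep(NA_integer_, n)
  if (length(models)) {
    q <- IRanges::IRanges(start = x$variants$pos,
                          end = x$variants$pos + nchar(x$variants$ref))
    s <- IRanges::IRanges(start = spans$start, end = spans$end)
    ov <- IRanges::findOverlaps(q, s, select = "first")
    same_chrom <- x$variants$chrom == spans$chrom[ifelse(is.na(ov), 1L, ov)]
    hits[!is.na(ov) & same_chrom] <- ov[!is.na(ov) & same_chrom]
  }
  for (i in seq_len(n)) {
    nv <- normalize_variant(x$variants$chrom[i], x$variants$pos[i],
                            x$variants$ref[i], x$variants$alt[i], genome)
    out$pos_vcf[i] <- nv$vcf$pos
    out$pos_hgvs[i] <- nv$hgvs_pos
    out$ref[i] <- nv$vcf$ref
    out$alt[i] <- nv$vcf$alt
    if (is.na(hits[i])) next
    cs <- tryCatch(call_consequence(nv, models[[hits[i]]], genome),
                   error = function(e) e)
    if (inherits(cs, "error")) {
      out$gene[i] <- models[[hits[i]]]$gene
      out$category[i] <- "unsupported"
      out$protein_changing[i] <- TRUE  # conservative: keep visible downstream
      next
    }
    out$gene[i] <- cs$gene
    out$category[i] <- cs$category
    out$hgvs_c[i] <- cs$hgvs_c
    out$hgvs_p[i] <- cs$hgvs_p
    out$truncated_fraction[i] <- cs$truncated_fraction
    out$protein_changing[i] <- cs$protein_changing
    out$near_splice[i] <- cs$near_splice
  }
  out
}
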