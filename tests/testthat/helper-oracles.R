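# Independent oracles. These deliberately avoid the package's own sequence
# machinery: reverse complement and string edits are re-implemented with base
# string ops, translation goes through seqinr (a different codebase than the
# Biostrings path the implementation uses).

o_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

o_apply <- function(seq, pos, ref, alt) {
  paste0(substr(seq, 1, pos - 1), alt, substr(seq, pos + nchar(ref), nchar(seq)))
}

o_translate <- function(s) {
  n <- nchar(s) - nchar(s) %% 3
  if (n < 3) return("")
  paste(seqinr::translate(seqinr::s2c(substr(s, 1, n))), collapse = "")
}

o_aaa <- function(a) if (a == "*") "*" else seqinr::aaa(a)

o_first_diff <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n > 0) {
    d <- which(utf8ToInt(substr(a, 1, n)) != utf8ToInt(substr(b, 1, n)))
    if (length(d)) return(d[1])
  }
  if (nchar(a) == nchar(b)) NA_integer_ else n + 1L
}

# --- brute-force placement enumeration (normalization oracle) ---------------

# rightmost q such that inserting len bases after position q of `seq`
# reproduces `mutant`; returns list(after, ins) or NULL
oracle_rightmost_ins <- function(seq, mutant, len) {
  for (q in nchar(seq):0) {
    S <- substr(mutant, q + 1, q + len)
    if (nchar(S) < len) next
    if (paste0(substr(seq, 1, q), S, substr(seq, q + 1, nchar(seq))) == mutant) {
      return(list(after = q, ins = S))
    }
  }
  NULL
}

oracle_leftmost_ins <- function(seq, mutant, len) {
  for (q in 0:nchar(seq)) {
    S <- substr(mutant, q + 1, q + len)
    if (nchar(S) < len) next
    if (paste0(substr(seq, 1, q), S, substr(seq, q + 1, nchar(seq))) == mutant) {
      return(list(after = q, ins = S))
    }
  }
  NULL
}

# rightmost / leftmost deletion start q (deleting seq[q..q+len-1]) giving mutant
oracle_rightmost_del <- function(seq, mutant, len) {
  for (q in (nchar(seq) - len + 1):1) {
    if (paste0(substr(seq, 1, q - 1), substr(seq, q + len, nchar(seq))) == mutant) {
      return(q)
    }
  }
  NULL
}

oracle_leftmost_del <- function(seq, mutant, len) {
  for (q in 1:(nchar(seq) - len + 1)) {
    if (paste0(substr(seq, 1, q - 1), substr(seq, q + len, nchar(seq))) == mutant) {
      return(q)
    }
  }
  NULL
}

# --- translate-and-diff consequence oracle ----------------------------------

# Rebuilds the mutant chromosome by plain string surgery, adjusts the CDS
# intervals, extracts and translates both CDS with seqinr, and classifies by
# protein comparison. `iv` is the ascending-genomic interval data frame; the
# planted edit must sit inside one exon.
oracle_consequence <- function(seq, iv, strand, pos, ref, alt) {
  delta <- nchar(alt) - nchar(ref)
  mutant <- o_apply(seq, pos, ref, alt)
  iv2 <- iv
  for (j in seq_len(nrow(iv2))) {
    if (iv2$start[j] > pos) iv2$start[j] <- iv2$start[j] + delta
    if (iv2$end[j] > pos) iv2$end[j] <- iv2$end[j] + delta
  }
  extract <- function(s, iv, strand) {
    ch <- vapply(seq_len(nrow(iv)),
                 function(j) substr(s, iv$start[j], iv$end[j]), "")
    if (strand == "-") paste(rev(vapply(ch, o_rc, "")), collapse = "")
    else paste(ch, collapse = "")
  }
  down <- function(s, iv, strand) {
    if (strand == "+") substr(s, max(iv$end) + 1, min(nchar(s), max(iv$end) + 3000))
    else o_rc(substr(s, max(1, min(iv$start) - 3000), min(iv$start) - 1))
  }
  wt_full <- o_translate(extract(seq, iv, strand))
  ws <- regexpr("*", wt_full, fixed = TRUE)
  wt <- if (ws > 0) substr(wt_full, 1, ws - 1) else wt_full
  mut_full <- o_translate(paste0(extract(mutant, iv2, strand),
                                 down(mutant, iv2, strand)))
  ms <- regexpr("*", mut_full, fixed = TRUE)
  has_stop <- ms > 0
  mut <- if (has_stop) substr(mut_full, 1, ms - 1) else mut_full
  wl <- nchar(wt); ml <- nchar(mut)

  if (delta %% 3 != 0) {
    i <- o_first_diff(paste0(wt, "*"), paste0(mut, if (has_stop) "*" else ""))
    if (is.na(i)) i <- wl + 1L
    wa <- if (i <= wl) o_aaa(substr(wt, i, i)) else "*"
    ma <- if (i <= ml) o_aaa(substr(mut, i, i)) else "*"
    hp <- if (ma == "*") sprintf("p.(%s%d*)", wa, i)
          else if (has_stop) sprintf("p.(%s%d%sfs*%d)", wa, i, ma, ml - i + 2L)
          else sprintf("p.(%s%d%sfs*?)", wa, i, ma)
    return(list(category = "frameshift", hgvs_p = hp))
  }
  if (identical(wt, mut) && has_stop && ml == wl) {
    return(list(category = "synonymous", hgvs_p = NA_character_))
  }
  if (!has_stop || ml > wl) {
    return(list(category = "stop_lost", hgvs_p = NA_character_))
  }
  if (delta == 0) {
    if (ml < wl) {
      i <- o_first_diff(wt, mut); if (is.na(i)) i <- ml + 1L
      return(list(category = "stop_gained",
                  hgvs_p = sprintf("p.(%s%d*)", o_aaa(substr(wt, i, i)), i)))
    }
    i <- o_first_diff(wt, mut)
    return(list(category = "missense",
                hgvs_p = sprintf("p.(%s%d%s)", o_aaa(substr(wt, i, i)), i,
                                 o_aaa(substr(mut, i, i)))))
  }
  if (ml < wl + delta %/% 3) {
    i <- o_first_diff(wt, mut); if (is.na(i)) i <- ml + 1L
    la <- if (i <= wl) o_aaa(substr(wt, i, i)) else "*"
    return(list(category = "stop_gained",
                hgvs_p = sprintf("p.(%s%d*)", la, i)))
  }
  list(category = if (delta > 0) "inframe_insertion" else "inframe_deletion",
       hgvs_p = NA_character_)
}

# Plant a random exonic variant on a gene model; returns NULL when the edit's
# repeat context makes any equivalent placement leave the exon (those are
# boundary cases the annotator reports as unsupported) or when it touches the
# start codon region.
plant_random_cds_variant <- function(seq, iv, strand) {
  j <- sample(nrow(iv), 1)
  start <- iv$start[j]; end <- iv$end[j]
  type <- sample(c("snv", "ins", "del"), 1)
  if (type == "snv") {
    p <- sample(start:end, 1)
    ref <- substr(seq, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    return(list(pos = p, ref = ref, alt = alt))
  }
  if (type == "ins") {
    if (end - start < 3) return(NULL)
    p <- sample((start + 1):(end - 1), 1)
    S <- random_dna(sample(1:3, 1))
    ref <- substr(seq, p, p)
    v <- list(pos = p, ref = ref, alt = paste0(ref, S))
    mutant <- o_apply(seq, v$pos, v$ref, v$alt)
    lm <- oracle_leftmost_ins(seq, mutant, nchar(S))
    rm <- oracle_rightmost_ins(seq, mutant, nchar(S))
    if (lm$after < start + 1 || rm$after > end - 1) return(NULL)
    return(v)
  }
  l <- sample(1:3, 1)
  if (end - start < l + 3) return(NULL)
  p <- sample(start:(end - l - 1), 1)  # anchor; deleted bases p+1..p+l
  v <- list(pos = p, ref = substr(seq, p, p + l), alt = substr(seq, p, p))
  mutant <- o_apply(seq, v$pos, v$ref, v$alt)
  lm <- oracle_leftmost_del(seq, mutant, l)
  rm <- oracle_rightmost_del(seq, mutant, l)
  if (lm < start || (rm + l - 1) > end) return(NULL)
  v
}

# CDS position of a genomic position, test-side (for start-codon guards)
o_g2c <- function(iv, strand, p) {
  ord <- if (strand == "+") order(iv$start) else order(-iv$start)
  off <- 0L
  for (j in ord) {
    if (p >= iv$start[j] && p <= iv$end[j]) {
      return(off + if (strand == "+") p - iv$start[j] + 1L else iv$end[j] - p + 1L)
    }
    off <- off + iv$end[j] - iv$start[j] + 1L
  }
  NA_integer_
}
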