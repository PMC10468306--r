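test_that("the engineered poly-C duplication annotates as c.698dup / p.(Ser235Glnfs*4)", {
  set.seed(42)
  fx <- single_exon_gene(causal_cds(6L))
  run_end <- fx$offset + 698L
  # left-aligned anchor-base representation, the way the aligner shows it
  anchor <- fx$offset + 692L
  nv <- normalize_variant("chr1", anchor, "A", "AC", fx$genome)
  expect_true(nv$is_duplication)
  expect_equal(nv$hgvs_pos, run_end)
  cs <- call_consequence(nv, fx$model, fx$genome)
  expect_equal(cs$category, "frameshift")
  expect_equal(cs$hgvs_c, "c.698dup")
  expect_equal(cs$hgvs_p, "p.(Ser235Glnfs*4)")
  expect_true(cs$protein_changing)
  expect_equal(truncation_fraction(cs), 1 - 237 / 1213, tolerance = 1e-12)
  # agrees with the seqinr-based translate-and-diff oracle
  orc <- oracle_consequence(fx$genome[["chr1"]],
                            data.frame(start = fx$offset + 1L,
                                       end = fx$offset + 3642L),
                            "+", anchor, "A", "AC")
  expect_equal(cs$category, orc$category)
  expect_equal(cs$hgvs_p, orc$hgvs_p)
})

test_that("an engineered CGA>CAA substitution annotates as p.(Arg795Gln)", {
  set.seed(43)
  cds <- random_cds(800L)
  substr(cds, 2383, 2385) <- "CGA"
  fx <- single_exon_gene(cds)
  pos <- fx$offset + 2384L
  nv <- normalize_variant("chr1", pos, "G", "A", fx$genome)
  cs <- call_consequence(nv, fx$model, fx$genome)
  expect_equal(cs$category, "missense")
  expect_equal(cs$hgvs_c, "c.2384G>A")
  expect_equal(cs$hgvs_p, "p.(Arg795Gln)")
})

test_that("third-position substitutions preserving the residue are synonymous", {
  set.seed(44)
  cds <- random_cds(100L)
  substr(cds, 31, 33) <- "GGA"  # codon 11: Gly
  fx <- single_exon_gene(cds)
  nv <- normalize_variant("chr1", fx$offset + 33L, "A", "G", fx$genome)
  cs <- call_consequence(nv, fx$model, fx$genome)
  expect_equal(cs$category, "synonymous")
  expect_false(cs$protein_changing)
  expect_equal(cs$hgvs_p, "p.(Gly11=)")
})

test_that("truncation fraction is the lost share of the reading frame", {
  set.seed(45)
  cds <- random_cds(1000L)
  substr(cds, 601, 603) <- "TGG"   # codon 201: Trp
  substr(cds, 2998, 3000) <- "TGG" # codon 1000: Trp
  fx <- single_exon_gene(cds)
  # stop at codon 201 removes 80% of a 1000-aa protein
  nv <- normalize_variant("chr1", fx$offset + 603L, "G", "A", fx$genome)  # TGG>TGA
  cs <- call_consequence(nv, fx$model, fx$genome)
  expect_equal(cs$category, "stop_gained")
  expect_equal(truncation_fraction(cs), 0.8, tolerance = 1e-12)
  # stop at the final codon removes almost nothing
  nv2 <- normalize_variant("chr1", fx$offset + 3000L, "G", "A", fx$genome)
  cs2 <- call_consequence(nv2, fx$model, fx$genome)
  expect_equal(cs2$category, "stop_gained")
  expect_equal(truncation_fraction(cs2), 1 / 1000, tolerance = 1e-12)
  # contract: only truncating consequences have a truncation fraction
  nv3 <- normalize_variant("chr1", fx$offset + 604L, substr(cds, 604, 604),
                           setdiff(c("A", "C", "G", "T"),
                                   substr(cds, 604, 604))[1], fx$genome)
  cs3 <- call_consequence(nv3, fx$model, fx$genome)
  expect_error(truncation_fraction(cs3), "truncating")
})

test_that("intergenic, intronic, near-splice and boundary-spanning calls are labelled", {
  set.seed(46)
  ex1 <- "ATGGCTCATAGC"; ex2 <- "GGATGGGCTTAA"
  intron <- paste0("GTC", random_dna(45), "AG")  # s[45] != s[40], no run across the junction
  genomic <- paste0(random_dna(30), ex1, intron, ex2, random_dna(30))
  g <- ref_genome(c(chr1 = genomic))
  iv <- data.frame(start = c(31L, 31L + 12L + 50L),
                   end = c(42L, 31L + 12L + 50L + 11L))
  m <- gene_model("NG", "tx-NG", "chr1", "+", iv)

  deep_intron <- 42L + 20L
  nv <- normalize_variant("chr1", deep_intron, substr(genomic, deep_intron, deep_intron),
                          setdiff(c("A", "C", "G", "T"),
                                  substr(genomic, deep_intron, deep_intron))[1], g)
  cs <- call_consequence(nv, m, g)
  expect_equal(cs$category, "intronic")
  expect_false(cs$protein_changing)
  expect_false(cs$near_splice)

  splice <- 43L  # first intronic base
  nv2 <- normalize_variant("chr1", splice, substr(genomic, splice, splice),
                           setdiff(c("A", "C", "G", "T"),
                                   substr(genomic, splice, splice))[1], g)
  cs2 <- call_consequence(nv2, m, g)
  expect_equal(cs2$category, "intronic")
  expect_true(cs2$near_splice)

  far <- 5L
  nv3 <- normalize_variant("chr1", far, substr(genomic, far, far),
                           setdiff(c("A", "C", "G", "T"),
                                   substr(genomic, far, far))[1], g)
  expect_equal(call_consequence(nv3, m, g)$category, "intergenic")

  # deletion spanning the exon 1 / intron boundary is unsupported, not dropped
  nv4 <- normalize_variant("chr1", 40L, substr(genomic, 40L, 45L), substr(genomic, 40L, 40L), g)
  expect_error(call_consequence(nv4, m, g), "unsupported")
  ch <- cohort(data.frame(chrom = "chr1", pos = 40L,
                          ref = substr(genomic, 40L, 45L),
                          alt = substr(genomic, 40L, 40L)),
               matrix("0/1", 1, 1, dimnames = list(NULL, "S1")))
  ann <- annotate_cohort(ch, list(m), g)
  expect_equal(ann$category, "unsupported")
})

test_that("random planted CDS variants agree with the translate-and-diff oracle", {
  set.seed(47)
  for (strand in c("+", "-")) {
    cds <- random_cds(180L)
    # two exons to exercise the projection
    genomic_parts <- if (strand == "+") {
      list(substr(cds, 1, 250), substr(cds, 251, nchar(cds)))
    } else {
      list(o_rc(substr(cds, 251, nchar(cds))), o_rc(substr(cds, 1, 250)))
    }
    intron <- random_dna(80)
    genomic <- paste0(random_dna(100), genomic_parts[[1]], intron,
                      genomic_parts[[2]], random_dna(100))
    l1 <- nchar(genomic_parts[[1]]); l2 <- nchar(genomic_parts[[2]])
    iv <- data.frame(start = c(101L, 101L + l1 + 80L),
                     end = c(100L + l1, 100L + l1 + 80L + l2))
    g <- ref_genome(c(chr1 = genomic))
    m <- gene_model("RG", "tx-RG", "chr1", strand, iv)
    expect_equal(cds_sequence(m, g), cds)  # construction sanity

    n_done <- 0
    while (n_done < 150) {
      v <- plant_random_cds_variant(genomic, iv, strand)
      if (is.null(v)) next
      cpos <- o_g2c(iv, strand, v$pos)
      if (!is.na(cpos) && cpos <= 6) next  # start-codon edits tested separately
      nv <- normalize_variant("chr1", v$pos, v$ref, v$alt, g)
      cs <- call_consequence(nv, m, g)
      orc <- oracle_consequence(genomic, iv, strand, v$pos, v$ref, v$alt)
      expect_equal(cs$category, orc$category,
                   label = sprintf("category at %s%d %s>%s", strand, v$pos,
                                   v$ref, v$alt))
      if (!is.na(orc$hgvs_p)) {
        expect_equal(cs$hgvs_p, orc$hgvs_p,
                     label = sprintf("hgvs_p at %s%d %s>%s", strand, v$pos,
                                     v$ref, v$alt))
      }
      n_done <- n_done + 1
    }
  }
})

test_that("reverse-complementing genome and model leaves hgvs_c/hgvs_p invariant", {
  set.seed(48)
  cds <- random_cds(150L)
  fx <- single_exon_gene(cds, flank = 120L)
  genomic <- fx$genome[["chr1"]]
  n <- nchar(genomic)
  g_rc <- ref_genome(c(chr1 = o_rc(genomic)))
  iv <- data.frame(start = fx$offset + 1L, end = fx$offset + nchar(cds))
  iv_rc <- data.frame(start = n - iv$end + 1L, end = n - iv$start + 1L)
  m_rc <- gene_model("TST", "tx-TST", "chr1", "-", iv_rc)

  n_done <- 0
  while (n_done < 40) {
    v <- plant_random_cds_variant(genomic, iv, "+")
    if (is.null(v)) next
    cpos <- o_g2c(iv, "+", v$pos)
    if (!is.na(cpos) && cpos <= 6) next
    cs <- call_consequence(normalize_variant("chr1", v$pos, v$ref, v$alt,
                                             fx$genome), fx$model, fx$genome)
    # mirror the same physical edit onto the reverse-complemented genome
    if (nchar(v$ref) == 1 && nchar(v$alt) == 1) {
      mv <- list(pos = n - v$pos + 1L, ref = o_rc(v$ref), alt = o_rc(v$alt))
    } else if (nchar(v$alt) > nchar(v$ref)) {           # insertion after pos
      S <- substr(v$alt, 2, nchar(v$alt))
      anchor <- n - v$pos
      b <- substr(o_rc(genomic), anchor, anchor)
      mv <- list(pos = anchor, ref = b, alt = paste0(b, o_rc(S)))
    } else {                                            # deletion of pos+1..pos+l
      l <- nchar(v$ref) - 1L
      anchor <- n - (v$pos + l)
      b <- substr(o_rc(genomic), anchor, anchor)
      mv <- list(pos = anchor, ref = paste0(b, o_rc(substr(v$ref, 2, l + 1L))),
                 alt = b)
    }
    cs_rc <- call_consequence(normalize_variant("chr1", mv$pos, mv$ref, mv$alt,
                                                g_rc), m_rc, g_rc)
    expect_equal(cs_rc$hgvs_c, cs$hgvs_c)
    expect_equal(cs_rc$hgvs_p, cs$hgvs_p)
    expect_equal(cs_rc$category, cs$category)
    n_done <- n_done + 1
  }
})
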