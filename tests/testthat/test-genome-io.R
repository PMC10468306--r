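test_that("FASTA reading loads, uppercases and validates sequences", {
  f <- write_tmp(c(">chr1", "ACGT"), ".fa")
  g <- read_fasta(f)
  expect_s3_class(g, "ref_genome")
  expect_equal(nchar(g[["chr1"]]), 4L)

  f2 <- write_tmp(c(">a", "acgt", ">b", "TTTT"), ".fa")
  g2 <- read_fasta(f2)
  expect_equal(sort(names(g2)), c("a", "b"))
  expect_equal(g2[["a"]], "ACGT")

  f3 <- write_tmp(c(">a", "ACGT", ">a", "TTTT"), ".fa")
  expect_error(read_fasta(f3), "duplicate")

  expect_error(ref_genome(c(x = "ACXT")), "offset 3")
})

test_that("multi-allelic VCF records split with per-allele genotype recoding", {
  # derived oracle: enumerate every unphased diploid GT over two alt alleles
  gts <- c("0/0", "0/1", "0/2", "1/1", "1/2", "2/2", "./.")
  rows <- lapply(seq_along(gts), function(i) {
    c("chr1", as.character(10 * i), "A", "C,T", gts[i])
  })
  f <- write_tmp(vcf_text("S1", rows), ".vcf")
  ch <- read_vcf(f)
  expect_equal(nrow(ch$variants), 2L * length(gts))
  for (i in seq_along(gts)) {
    al <- suppressWarnings(as.integer(strsplit(gts[i], "/")[[1]]))
    for (k in 1:2) {
      expected <- if (anyNA(al)) "./." else c("0/0", "0/1", "1/1")[sum(al == k) + 1L]
      row <- which(ch$variants$pos == 10 * i &
                     ch$variants$alt == c("C", "T")[k])
      expect_length(row, 1L)
      expect_equal(unname(ch$gt[row, "S1"]), expected,
                   label = sprintf("GT %s vs alt %d", gts[i], k))
    }
  }
})

test_that("multi-allelic splitting conserves non-reference allele counts", {
  set.seed(11)
  for (rep in 1:25) {
    n_alt <- sample(2:3, 1)
    gts <- replicate(6, paste(sort(sample(0:n_alt, 2, replace = TRUE)),
                              collapse = "/"))
    alts <- paste(c("C", "G", "T")[seq_len(n_alt)], collapse = ",")
    f <- write_tmp(vcf_text(sprintf("S%d", 1:6),
                            list(c("chr1", "5", "A", alts, gts))), ".vcf")
    ch <- read_vcf(f)
    orig_nonref <- sum(unlist(strsplit(gts, "/")) != "0")
    split_nonref <- sum(ch$gt == "0/1") + 2L * sum(ch$gt == "1/1")
    expect_equal(split_nonref, orig_nonref)
  }
})

test_that("VCF parsing rejects malformed genotype data", {
  f <- write_tmp(vcf_text("S1", list(c("chr1", "5", "A", "C", "12")),
                          format = "DP"), ".vcf")
  expect_error(read_vcf(f), "GT")
  f2 <- write_tmp(vcf_text("S1", list(c("chr1", "5", "A", "C", "0/3"))), ".vcf")
  expect_error(read_vcf(f2), "out of range")
  f3 <- write_tmp(vcf_text("S1", list(c("chr1", "5", "A", "C", "0|1"))), ".vcf")
  expect_error(read_vcf(f3), "phased")
})

test_that("VCF write -> read is the identity on the data model", {
  set.seed(7)
  n <- 10L
  vars <- data.frame(chrom = "chr1", pos = sort(sample(1000, n)),
                     ref = sample(c("A", "C", "GT", "T"), n, replace = TRUE),
                     alt = sample(c("G", "TA", "C"), n, replace = TRUE))
  vars$alt[vars$alt == vars$ref] <- "CCA"
  gt <- matrix(sample(c("0/0", "0/1", "1/1", "./."), n * 4, replace = TRUE),
               nrow = n, dimnames = list(NULL, sprintf("S%d", 1:4)))
  ch <- cohort(vars, gt)
  f <- tempfile(fileext = ".vcf")
  write_vcf(ch, f)
  ch2 <- read_vcf(f)
  expect_equal(ch2$variants, ch$variants)
  expect_equal(ch2$gt, ch$gt)
  expect_equal(ch2$samples, ch$samples)
})

test_that("minus-strand GFF3 models come back in transcript order", {
  # hand-built 2-exon minus-strand gene: CDS must equal the reverse
  # complement of the concatenated genomic intervals
  set.seed(3)
  ex2 <- "ATGGCTCAT"; ex1 <- "GGATGGTAA"  # transcript order: ex2 then ex1? no:
  # transcript: ATGGCTCAT + GGATGGTAA reads 5'->3'; on the minus strand the
  # first transcript exon occupies the higher genomic coordinates
  intron <- random_dna(20)
  genomic <- paste0(random_dna(10), o_rc(ex1), intron, o_rc(ex2), random_dna(10))
  g <- ref_genome(c(chr1 = genomic))
  iv <- data.frame(start = c(11L, 11L + 9L + 20L),
                   end = c(11L + 8L, 11L + 9L + 20L + 8L))
  m <- gene_model("MG", "tx-MG", "chr1", "-", iv)
  expect_equal(m$cds$start, rev(sort(iv$start)))  # transcript order descending
  expect_equal(cds_sequence(m, g), paste0(ex2, ex1))
  expect_equal(cds_sequence(m, g),
               o_rc(paste0(substr(genomic, 11, 19),
                           substr(genomic, 40, 48))))
  f <- tempfile(fileext = ".gff3")
  write_gff3(list(m), f)
  m2 <- read_gff3(f)[[1]]
  expect_equal(m2$cds, m$cds)
  expect_equal(m2$strand, "-")
  expect_equal(m2$gene, "MG")
})

test_that("gene model invariants are enforced", {
  iv_bad <- data.frame(start = c(1, 5), end = c(6, 9))
  expect_error(gene_model("X", "tx", "chr1", "+", iv_bad), "overlap")
  iv_len <- data.frame(start = 1, end = 4)
  expect_error(gene_model("X", "tx", "chr1", "+", iv_len), "divisible by 3")
  g <- ref_genome(c(chr1 = "TTTACGTTTAGG"))
  expect_warning(gene_model("X", "tx", "chr1", "+",
                            data.frame(start = 1, end = 6), genome = g),
                 "clean ORF")
})

test_that("PED reading validates structure and round-trips", {
  f <- write_tmp(c("FAM1\tSIRE\t0\t0\t1\t1",
                   "FAM1\tDAM\t0\t0\t2\t1",
                   "FAM1\tKID\tSIRE\tDAM\t2\t2"), ".ped")
  p <- read_ped(f)
  expect_equal(nrow(p), 3L)
  expect_equal(p$affected[p$id == "KID"], "affected")
  expect_equal(p$sire[p$id == "KID"], "SIRE")
  f2 <- tempfile(fileext = ".ped")
  write_ped(p, f2)
  expect_equal(read_ped(f2), p)

  f3 <- write_tmp(c("F\tA\tGHOST\t0\t1\t1"), ".ped")
  expect_error(read_ped(f3), "unresolved")
  f4 <- write_tmp(c("F\tA\tB\t0\t1\t1", "F\tB\tA\t0\t1\t1"), ".ped")
  expect_error(read_ped(f4), "cyclic")
})

test_that("gene lists and TSV tables respect comments and schemas", {
  f <- write_tmp(c("# candidates", "ADAMTS2", "COL1A2 # decoy", "", "COL5A1"),
                 ".txt")
  expect_equal(read_gene_list(f), c("ADAMTS2", "COL1A2", "COL5A1"))
  f2 <- write_tmp(c("name\tforward", "a\tACGT"), ".tsv")
  expect_error(read_tsv_table(f2, required = c("name", "reverse")), "reverse")
})
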