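test_that("in-silico PCR finds the hand-counted amplicon on a toy template", {
  set.seed(51)
  # 40-bp template: forward primer at 5..12, reverse site at 27..34
  seq <- random_dna(40)
  fwd <- substr(seq, 5, 12)
  rev <- o_rc(substr(seq, 27, 34))
  pp <- primer_pair("toy", fwd, rev, max_product = 100L)
  amp <- insilico_pcr(seq, pp)
  if (nrow(amp) == 1L) {  # random flanks could in principle duplicate a site
    expect_equal(amp$start, 5L)
    expect_equal(amp$end, 34L)
    expect_equal(amp$length, 30L)
  }
  expect_gte(nrow(amp), 1L)

  # a 1-bp insertion between the primer sites lengthens the product by 1
  seq_ins <- paste0(substr(seq, 1, 20), "A", substr(seq, 21, 40))
  amp2 <- insilico_pcr(seq_ins, pp)
  expect_equal(amp2$length[1], 31L)

  # absent forward primer: no product
  expect_equal(nrow(insilico_pcr(random_dna(40), pp)), 0L)
})

test_that("primer validation rejects non-DNA input", {
  expect_error(primer_pair("bad", "ACGU", "ACGT"), "is_dna")
  expect_error(primer_pair("bad", "", "ACGT"))
})

test_that("amplicons respect max_product and both orientations are searched", {
  seq <- paste0("AAAAAAAA", "ACGTACGTGG", strrep("T", 50), "CCATGCATGC", "AAAAAAAA")
  fwd <- "ACGTACGTGG"
  rev <- o_rc("CCATGCATGC")
  amp <- insilico_pcr(seq, primer_pair("x", fwd, rev, max_product = 1000L))
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 70L)
  expect_equal(nrow(insilico_pcr(seq, primer_pair("x", fwd, rev,
                                                  max_product = 50L))), 0L)
  # swapping forward and reverse still finds the product (opposite strand)
  amp_sw <- insilico_pcr(seq, primer_pair("x", rev, fwd, max_product = 1000L))
  expect_equal(amp_sw$length, 70L)
  expect_equal(amp_sw$orientation, "reverse")
})

test_that("the genotyping assay sizes the wild-type and mutant alleles 1 bp apart", {
  sim <- fixture_sim()
  pp <- sim$primers[[1]]
  amp_ref <- insilico_pcr(sim$genome, pp)
  expect_equal(nrow(amp_ref), 1L)
  expect_equal(amp_ref$length, 169L)
  tr <- sim$truth$causal
  mut <- apply_variant(sim$genome, tr$chrom, tr$pos, tr$ref, tr$alt)
  amp_mut <- insilico_pcr(mut, pp)
  expect_equal(amp_mut$length, 170L)
})

test_that("single-parent and trio locus exclusion logic is correct", {
  mk <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r) {
      data.frame(sample = r[[1]], locus = r[[2]], allele1 = r[[3]],
                 allele2 = r[[4]], stringsAsFactors = FALSE)
    }))
  }
  m <- mk(list("KID", "L1", 150L, 154L), list("SIRE", "L1", 150L, 152L))
  expect_true(parentage_exclusion(m, "KID", "SIRE")$compatible)

  m2 <- mk(list("KID", "L1", 150L, 154L), list("SIRE", "L1", 156L, 158L))
  r2 <- parentage_exclusion(m2, "KID", "SIRE")
  expect_false(r2$compatible)
  expect_equal(r2$excluded_loci, "L1")

  # trio: offspring 150/150 needs a 150 from BOTH parents
  m3 <- mk(list("KID", "L1", 150L, 150L), list("SIRE", "L1", 150L, 152L),
           list("DAM", "L1", 154L, 156L))
  expect_false(parentage_exclusion(m3, "KID", "SIRE", "DAM")$compatible)
  # single-parent views of the same data are each compatible
  expect_true(parentage_exclusion(m3, "KID", "SIRE")$compatible)

  # missing loci are skipped and not counted
  m4 <- rbind(m, mk(list("KID", "L2", NA, NA), list("SIRE", "L2", 150L, 150L)))
  expect_equal(parentage_exclusion(m4, "KID", "SIRE")$loci_tested, 1L)
  expect_error(parentage_exclusion(m[m$sample == "KID", ], "KID", "SIRE"),
               "no shared genotyped locus")
})

test_that("the simulated sire is compatible with every affected kitten", {
  sim <- fixture_sim()
  affected <- sim$ped$id[sim$ped$affected == "affected"]
  expect_length(affected, 4L)
  for (k in affected) {
    dam <- sim$ped$dam[sim$ped$id == k]
    r <- parentage_exclusion(sim$markers, k, "SIRE", dam)
    expect_true(r$compatible, label = k)
    expect_equal(r$loci_tested, 16L)
  }
})
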