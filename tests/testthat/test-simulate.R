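test_that("identical config and seed give byte-identical artifacts", {
  cfg <- sim_config(seed = 5L, n_background_variants = 150L)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  simulate_cohort(cfg, outdir = d1)
  simulate_cohort(cfg, outdir = d2)
  for (f in c("reference.fa", "genes.gff3", "cohort.vcf", "family.vcf",
              "pedigree.ped", "markers.tsv", "primers.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("the causal gene carries the configured homopolymer run in its CDS", {
  for (L in c(4L, 6L, 9L)) {
    ref <- simulate_reference(sim_config(seed = 6L, homopolymer_length = L))
    m1 <- ref$models[[which(vapply(ref$models, `[[`, "", "gene") == "CAND01")]]
    cds <- cds_sequence(m1, ref$genome)
    expect_true(grepl(strrep("C", L), cds, fixed = TRUE))
    expect_equal(substr(cds, 699L - L, 698L), strrep("C", L))
    expect_false(substr(cds, 698L - L, 698L - L) == "C")  # run is exactly L
    run <- genome_slice(ref$genome, "chr1", ref$causal$run_start,
                        ref$causal$run_end)
    expect_equal(run, strrep("C", L))
  }
})

test_that("every generated gene model encodes a clean ORF (seqinr oracle)", {
  ref <- simulate_reference(sim_config(seed = 8L))
  expect_length(ref$models, 80L)
  for (m in ref$models) {
    p <- o_translate(cds_sequence(m, ref$genome))
    expect_equal(substr(p, 1, 1), "M", label = m$gene)
    expect_equal(substr(p, nchar(p), nchar(p)), "*", label = m$gene)
    expect_false(grepl("*", substr(p, 1, nchar(p) - 1), fixed = TRUE),
                 label = m$gene)
  }
})

test_that("the study-family template has 31 genotyped cats with 4 affected", {
  pr <- simulate_pedigree(default_config())
  expect_equal(nrow(pr$ped), 31L)
  expect_equal(sum(pr$ped$affected == "affected"), 4L)
  expect_length(pr$causal_gt, 31L)
  cls <- gt_class(pr$causal_gt)
  expect_equal(unname(c(sum(cls == "hom_alt"), sum(cls == "het"),
                        sum(cls == "hom_ref"))), c(4L, 20L, 7L))
  # every affected kitten has two heterozygous (obligate carrier) parents
  for (id in pr$ped$id[pr$ped$affected == "affected"]) {
    sire <- pr$ped$sire[pr$ped$id == id]; dam <- pr$ped$dam[pr$ped$id == id]
    expect_equal(unname(pr$causal_gt[sire]), "0/1")
    expect_equal(unname(pr$causal_gt[dam]), "0/1")
  }
  # affection status is genotype-determined
  expect_equal(pr$ped$affected == "affected",
               unname(pr$causal_gt[pr$ped$id] == "1/1"))
})

test_that("custom litter sizes drop genotypes consistent with the parents", {
  cfg <- sim_config(seed = 9L, pedigree_template = "custom",
                    litter_sizes = c(5L, 4L, 6L))
  pr <- simulate_pedigree(cfg)
  expect_equal(nrow(pr$ped), 4L + 15L)
  # exhaustive trio check against the Mendelian transmission table
  for (i in seq_len(nrow(pr$ped))) {
    id <- pr$ped$id[i]
    s <- pr$ped$sire[i]; d <- pr$ped$dam[i]
    if (is.na(s)) next
    child <- sort(as.integer(strsplit(pr$causal_gt[[id]], "/")[[1]]))
    sa <- as.integer(strsplit(pr$causal_gt[[s]], "/")[[1]])
    da <- as.integer(strsplit(pr$causal_gt[[d]], "/")[[1]])
    ok <- FALSE
    for (x in sa) for (y in da) if (identical(sort(c(x, y)), child)) ok <- TRUE
    expect_true(ok, label = sprintf("trio %s", id))
  }
})

test_that("planted genotypes match the intended scenario", {
  sim <- fixture_sim()
  key <- variant_key(sim$cohort$variants)
  tr <- sim$truth
  causal_i <- match(paste(tr$causal$chrom, tr$causal$pos, tr$causal$ref,
                          tr$causal$alt, sep = ":"), key)
  decoy_i <- match(paste(tr$decoy_missense$chrom, tr$decoy_missense$pos,
                         tr$decoy_missense$ref, tr$decoy_missense$alt,
                         sep = ":"), key)
  expect_false(anyNA(c(causal_i, decoy_i)))
  expect_equal(unname(sim$cohort$gt[causal_i, sim$case_id]), "1/1")
  expect_equal(unname(sim$cohort$gt[decoy_i, sim$case_id]), "0/1")
  # all 77 controls are hom-ref or missing at both planted sites
  for (i in c(causal_i, decoy_i)) {
    expect_true(all(gt_class(sim$cohort$gt[i, sim$control_ids]) %in%
                      c("hom_ref", "missing")))
  }
  # the non-cosegregating decoy is homozygous in at least one unaffected cat
  fam_key <- variant_key(sim$family$variants)
  nc_i <- match(paste(tr$noncoseg$chrom, tr$noncoseg$pos, tr$noncoseg$ref,
                      tr$noncoseg$alt, sep = ":"), fam_key)
  unaff <- sim$ped$id[sim$ped$affected == "unaffected"]
  expect_gte(sum(sim$family$gt[nc_i, unaff] == "1/1"), 1L)
  # the case is never missing
  expect_false(any(sim$cohort$gt[, sim$case_id] == "./."))
})

test_that("background control allele frequencies follow the configured Beta", {
  cfg <- sim_config(seed = 10L, n_background_variants = 2000L)
  ref <- simulate_reference(cfg)
  pr <- simulate_pedigree(cfg)
  pv <- plant_variants(cfg, ref, pr)
  f <- pv$truth$background$freq
  expect_length(f, 2000L)
  a <- cfg$af_beta[1]; b <- cfg$af_beta[2]
  mu <- a / (a + b)
  se <- sqrt(a * b / ((a + b)^2 * (a + b + 1))) / sqrt(length(f))
  expect_lt(abs(mean(f) - mu), 3 * se)
})

test_that("marker panels are Mendelian over the pedigree", {
  sim <- fixture_sim()
  expect_equal(length(unique(sim$markers$locus)), 16L)
  expect_equal(length(unique(sim$markers$sample)), 31L)
  for (i in seq_len(nrow(sim$ped))) {
    id <- sim$ped$id[i]
    s <- sim$ped$sire[i]; d <- sim$ped$dam[i]
    if (is.na(s)) next
    for (loc in unique(sim$markers$locus)) {
      o <- marker_alleles(sim$markers, id, loc)
      expect_gte(length(intersect(o, marker_alleles(sim$markers, s, loc))), 1L)
      expect_gte(length(intersect(o, marker_alleles(sim$markers, d, loc))), 1L)
    }
  }
})
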