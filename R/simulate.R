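# Synthetic study stand-in: a mini reference with a candidate-gene panel, a
# causal homozygous 1-bp duplication inside a CDS poly-C run of candidate
# gene 1, a heterozygous decoy missense in candidate gene 2, a
# non-cosegregating decoy in candidate gene 3, Beta-distributed background
# variation across the control panel, the study-family pedigree (1 sire, 3
# dams, 3 litters, 31 genotyped cats, 4 affected), a 16-locus microsatellite
# panel and genotyping primers. Everything is deterministic given the seed;
# the stages consume seed, seed+1, seed+2, seed+3 in that order.

STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_pool <- function() {
  all <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T"), paste0)),
                         c("A", "C", "G", "T"), paste0))
  setdiff(all, STOP_CODONS)
}

random_cds <- function(n_aa) {
  paste0("ATG",
         paste(sample(codon_pool(), n_aa - 1L, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Simulation configuration
#'
#' Defaults mirror the emulated study: one case against 77 control genomes,
#' 48 unrelated genotyping controls, 20 functional candidate genes, and a
#' family of 31 genotyped cats (1 sire, 3 dams, 3 litters, 4 affected).
#'
#' @param seed Integer; fixes all downstream randomness.
#' @param n_controls Control genomes in the filtering panel.
#' @param n_genotyping_controls Unrelated cats genotyped for the causal
#'   variant by the confirmation assay.
#' @param n_candidate_genes Candidate genes (symbols `CAND01`...).
#' @param n_background_genes Non-candidate genes (symbols `BKGD01`...).
#' @param n_background_variants Background biallelic SNVs.
#' @param af_beta Length-2 numeric, shape parameters of the Beta distribution
#'   of control-panel allele frequencies.
#' @param missing_genotype_rate Per-genotype missingness probability for
#'   controls (never applied to the case).
#' @param homopolymer_length Length of the poly-C run hosting the causal
#'   duplication (4 to 40; the run must fit inside one exon).
#' @param pedigree_template `"study_family"` or `"custom"`.
#' @param litter_sizes Integer vector of litter sizes (3 litters of 9 for the
#'   study-family template).
#' @param protein_length_range,intron_length_range,intergenic_gap_range
#'   Sampling ranges (amino acids / bp) for gene geometry.
#' @param max_chromosome_length Sizing guard; generation fails if the
#'   requested genes do not fit.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_controls = 77L,
                       n_genotyping_controls = 48L,
                       n_candidate_genes = 20L,
                       n_background_genes = 60L,
                       n_background_variants = 1000L,
                       af_beta = c(0.3, 3),
                       missing_genotype_rate = 0.02,
                       homopolymer_length = 6L,
                       pedigree_template = c("study_family", "custom"),
                       litter_sizes = c(9L, 9L, 9L),
                       protein_length_range = c(150L, 400L),
                       intron_length_range = c(100L, 300L),
                       intergenic_gap_range = c(2000L, 6000L),
                       max_chromosome_length = 5e6) {
  pedigree_template <- match.arg(pedigree_template)
  stopifnot(length(af_beta) == 2, all(af_beta > 0),
            missing_genotype_rate >= 0, missing_genotype_rate <= 1,
            n_controls >= 0, n_background_variants >= 0,
            n_candidate_genes >= 3,  # causal + two decoy hosts
            homopolymer_length >= 4, homopolymer_length <= 40,  # run must fit inside exon 4 of the causal gene
            all(litter_sizes >= 1))
  structure(list(seed = as.integer(seed), n_controls = as.integer(n_controls),
                 n_genotyping_controls = as.integer(n_genotyping_controls),
                 n_candidate_genes = as.integer(n_candidate_genes),
                 n_background_genes = as.integer(n_background_genes),
                 n_background_variants = as.integer(n_background_variants),
                 af_beta = as.numeric(af_beta),
                 missing_genotype_rate = missing_genotype_rate,
                 homopolymer_length = as.integer(homopolymer_length),
                 pedigree_template = pedigree_template,
                 litter_sizes = as.integer(litter_sizes),
                 protein_length_range = as.integer(protein_length_range),
                 intron_length_range = as.integer(intron_length_range),
                 intergenic_gap_range = as.integer(intergenic_gap_range),
                 max_chromosome_length = max_chromosome_length),
            class = "sim_config")
}

# Engineered causal CDS: a 1213-aa protein whose poly-C run ends at CDS
# position 698, so that duplicating one C is annotated c.698dup and
# translates to p.(Ser235Glnfs*4), truncating ~80% of the open reading frame.
causal_cds <- function(L) {
  n_aa <- 1213L
  s <- strsplit(random_cds(n_aa), "")[[1]]
  g <- 698L - L                     # guard position: last base before the run
  stopifnot(g >= 4L)
  cstart <- g - ((g - 1L) %% 3L)    # codon-aligned start of the overwrite
  s[cstart:g] <- "A"
  s[(g + 1L):698L] <- "C"
  s[699:714] <- c("G", "G", "G", "C", "A", "G", "T", "C",
                  "A", "C", "C", "A", "T", "A", "A", "A")
  paste(s, collapse = "")
}

# split a CDS length into exon chunk lengths
exon_chunks <- function(cds_len, n_exons) {
  if (n_exons == 1L) return(cds_len)
  cuts <- sort(sample(seq_len(cds_len - 1L), n_exons - 1L))
  diff(c(0L, cuts, cds_len))
}

# lay one gene down on the chromosome; returns genomic sequence and the
# ascending CDS intervals relative to `offset` (last base before the gene)
place_gene <- function(cds_seq, strand, chunk_lens, intron_lens, offset) {
  k <- length(chunk_lens)
  stopifnot(length(intron_lens) == k - 1L || k == 1L)
  starts_tx <- cumsum(c(1L, chunk_lens[-k]))
  chunks_tx <- substring(cds_seq, starts_tx, starts_tx + chunk_lens - 1L)
  if (strand == "+") {
    exon_seqs <- chunks_tx
    tx_index <- seq_len(k)
  } else {
    exon_seqs <- revcomp(chunks_tx[k:1])
    tx_index <- k:1
  }
  pieces <- character(0)
  iv <- data.frame(start = integer(k), end = integer(k))
  cursor <- offset
  for (i in seq_len(k)) {
    iv$start[i] <- cursor + 1L
    iv$end[i] <- cursor + nchar(exon_seqs[i])
    cursor <- iv$end[i]
    pieces <- c(pieces, exon_seqs[i])
    if (i < k) {
      intr <- random_dna(intron_lens[i])
      pieces <- c(pieces, intr)
      cursor <- cursor + nchar(intr)
    }
  }
  list(seq = paste(pieces, collapse = ""), intervals = iv, tx_index = tx_index)
}

# CDS position -> genomic position for a gene model
c2g <- function(model, cpos) {
  off <- cds_offsets(model)
  lens <- model$cds$end - model$cds$start + 1L
  for (i in seq_along(lens)) {
    if (cpos > off[i] && cpos <= off[i] + lens[i]) {
      d <- cpos - off[i]
      return(if (model$strand == "+") model$cds$start[i] + d - 1L
             else model$cds$end[i] - d + 1L)
    }
  }
  stop("CDS position out of range: ", cpos)
}

#' Simulate the mini reference genome, gene models and candidate-gene panel
#'
#' One chromosome carrying `n_candidate_genes` candidate genes (causal gene
#' `CAND01` hosts the engineered poly-C run) and `n_background_genes`
#' background genes, shuffled along the chromosome with random intergenic
#' gaps. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List: `genome` ([ref_genome()]), `models` (list of
#'   [gene_model()]), `candidate_genes`, `causal` (gene/transcript/run
#'   coordinates of the engineered homopolymer).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$homopolymer_length
  cand <- sprintf("CAND%02d", seq_len(config$n_candidate_genes))
  bkgd <- if (config$n_background_genes > 0) {
    sprintf("BKGD%02d", seq_len(config$n_background_genes))
  } else character(0)
  gene_order <- sample(c(cand, bkgd))

  pieces <- character(0)
  cursor <- 0L
  models <- list()
  causal <- NULL
  for (g in gene_order) {
    gap <- sample(config$intergenic_gap_range[1]:config$intergenic_gap_range[2], 1L)
    pieces <- c(pieces, random_dna(gap))
    cursor <- cursor + gap
    if (g == "CAND01") {
      cds <- causal_cds(L)
      chunk_lens <- c(200L, 200L, 250L, 300L, rep(673L, 4L))  # run sits in exon 4
      strand <- "+"
    } else {
      n_aa <- sample(config$protein_length_range[1]:config$protein_length_range[2], 1L)
      cds <- random_cds(n_aa)
      n_ex <- sample(2:6, 1L)
      chunk_lens <- exon_chunks(nchar(cds), n_ex)
      strand <- sample(c("+", "-"), 1L)
    }
    intron_lens <- if (length(chunk_lens) > 1L) {
      sample(config$intron_length_range[1]:config$intron_length_range[2],
             length(chunk_lens) - 1L, replace = TRUE)
    } else integer(0)
    pl <- place_gene(cds, strand, chunk_lens, intron_lens, cursor)
    pieces <- c(pieces, pl$seq)
    cursor <- cursor + nchar(pl$seq)
    tx <- paste0("tx-", g)
    models[[tx]] <- gene_model(g, tx, "chr1", strand, pl$intervals)
    if (cursor > config$max_chromosome_length) {
      stop("requested genes do not fit max_chromosome_length")
    }
  }
  tail_gap <- sample(config$intergenic_gap_range[1]:config$intergenic_gap_range[2], 1L)
  pieces <- c(pieces, random_dna(tail_gap))
  genome <- ref_genome(c(chr1 = paste(pieces, collapse = "")))

  m1 <- models[["tx-CAND01"]]
  run_start_g <- c2g(m1, 699L - L)
  run_end_g <- c2g(m1, 698L)
  stopifnot(genome_slice(genome, "chr1", run_start_g, run_end_g) ==
              strrep("C", L),
            genome_base(genome, "chr1", run_start_g - 1L) != "C",
            genome_base(genome, "chr1", run_end_g + 1L) != "C")
  list(genome = genome, models = unname(models),
       candidate_genes = cand,
       causal = list(gene = "CAND01", transcript = "tx-CAND01",
                     run_start = run_start_g, run_end = run_end_g,
                     run_cds_end = 698L, homopolymer_length = L))
}

# ---- pedigree ---------------------------------------------------------------

#' Simulate the study-family pedigree with causal-site genotypes
#'
#' The `study_family` template reproduces the emulated family: one sire,
#' three dams (all four founders obligate het carriers), three litters, 31
#' genotyped individuals of which exactly 4 are affected; causal genotypes
#' are fixed so that the family tabulates as 4 affected homozygotes, 20
#' heterozygotes and 7 wild-type homozygotes. With `pedigree_template =
#' "custom"` the litter sizes come from `config$litter_sizes` and offspring
#' genotypes are drawn by Mendelian transmission from het x het crosses
#' (affection status assigned iff homozygous alternate; fully penetrant).
#'
#' @param config A [sim_config()].
#' @return List: `ped` ([pedigree()]), `causal_gt` (named genotype vector),
#'   `founders`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  founders <- data.frame(
    id = c("SIRE", "DAM1", "DAM2", "DAM3"),
    sire = NA_character_, dam = NA_character_,
    sex = c("male", "female", "female", "female"),
    affected = "unaffected", stringsAsFactors = FALSE)
  sizes <- config$litter_sizes
  rows <- founders
  ids <- list()
  for (l in seq_along(sizes)) {
    kid_ids <- sprintf("L%dK%d", l, seq_len(sizes[l]))
    ids[[l]] <- kid_ids
    rows <- rbind(rows, data.frame(
      id = kid_ids, sire = "SIRE", dam = paste0("DAM", ((l - 1L) %% 3L) + 1L),
      sex = rep(c("male", "female"), length.out = sizes[l]),
      affected = "unaffected", stringsAsFactors = FALSE))
  }
  gt <- stats::setNames(rep("0/1", 4L), founders$id)  # obligate carriers
  if (config$pedigree_template == "study_family" &&
      identical(sizes, c(9L, 9L, 9L))) {
    litter_gt <- list(
      c("1/1", "1/1", "0/1", "0/1", "0/1", "0/1", "0/0", "0/0", "0/0"),
      c("1/1", "0/1", "0/1", "0/1", "0/1", "0/1", "0/1", "0/0", "0/0"),
      c("1/1", "0/1", "0/1", "0/1", "0/1", "0/1", "0/1", "0/0", "0/0"))
    for (l in 1:3) gt[ids[[l]]] <- litter_gt[[l]]
  } else {
    for (l in seq_along(sizes)) {
      a1 <- sample(0:1, sizes[l], replace = TRUE)  # from sire (het)
      a2 <- sample(0:1, sizes[l], replace = TRUE)  # from dam (het)
      gt[ids[[l]]] <- c("0/0", "0/1", "1/1")[a1 + a2 + 1L]
    }
  }
  rows$affected <- ifelse(gt[rows$id] == "1/1", "affected", "unaffected")
  list(ped = pedigree(rows), causal_gt = gt, founders = founders$id)
}

# ---- variants ---------------------------------------------------------------

draw_hwe_gt <- function(n, f) {
  a <- stats::rbinom(n, 1L, f) + stats::rbinom(n, 1L, f)
  c("0/0", "0/1", "1/1")[a + 1L]
}

# pick a missense substitution inside a gene model; returns the genomic
# record plus expected annotation bits
pick_missense <- function(model, genome, codon) {
  cds <- cds_sequence(model, genome)
  stopifnot(codon * 3L <= nchar(cds) - 3L)
  for (off in c(2L, 1L, 3L)) {
    cpos <- (codon - 1L) * 3L + off
    ref_b <- substr(cds, cpos, cpos)
    wt_codon <- substr(cds, (codon - 1L) * 3L + 1L, codon * 3L)
    for (alt_b in setdiff(c("A", "C", "G", "T"), ref_b)) {
      mut_codon <- wt_codon
      substr(mut_codon, off, off) <- alt_b
      wt_aa <- translate_dna(wt_codon); mut_aa <- translate_dna(mut_codon)
      if (mut_aa != wt_aa && mut_aa != "*" && wt_aa != "*") {
        gpos <- c2g(model, cpos)
        g_ref <- genome_base(genome, model$chrom, gpos)
        g_alt <- if (model$strand == "-") revcomp(alt_b) else alt_b
        stopifnot(g_ref == (if (model$strand == "-") revcomp(ref_b) else ref_b))
        return(list(chrom = model$chrom, pos = gpos, ref = g_ref, alt = g_alt,
                    cpos = cpos, codon = codon, wt_aa = wt_aa, mut_aa = mut_aa))
      }
    }
  }
  stop("no missense substitution found in codon ", codon, " of ", model$gene)
}

#' Plant the causal and decoy variants and background variation
#'
#' Emits the case + control cohort (causal homozygous duplication written
#' left-aligned at the anchor base before the poly-C run, the way an
#' alignment viewer shows it; heterozygous decoy missense private to the
#' case; a non-cosegregating decoy carried by some controls; Beta-frequency
#' background SNVs), the 31-member family genotypes at the two sites used for
#' segregation analysis, and the unrelated genotyping-control panel.
#' Genotype missingness is applied to controls only, never to the case, and
#' never to the planted carriers of the non-cosegregating decoy.
#'
#' @param config A [sim_config()].
#' @param ref Result of [simulate_reference()].
#' @param pedres Result of [simulate_pedigree()].
#' @return List: `cohort`, `family`, `genotyping_controls`, `case_id`,
#'   `control_ids`, `truth`.
#' @export
plant_variants <- function(config, ref, pedres) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  genome <- ref$genome
  models <- ref$models
  model_of <- function(g) models[[which(vapply(models, `[[`, "", "gene") == g)]]

  affected <- pedres$ped$id[pedres$ped$affected == "affected"]
  stopifnot(length(affected) >= 1)
  case_id <- affected[1]
  control_ids <- sprintf("CTRL%02d", seq_len(config$n_controls))

  m1 <- model_of("CAND01")
  anchor <- ref$causal$run_start - 1L
  anchor_base <- genome_base(genome, "chr1", anchor)
  causal_rec <- data.frame(chrom = "chr1", pos = anchor, ref = anchor_base,
                           alt = paste0(anchor_base, "C"),
                           stringsAsFactors = FALSE)

  m2 <- model_of("CAND02")
  n_aa2 <- (sum(m2$cds$end - m2$cds$start + 1L) / 3L) - 1L
  decoy <- pick_missense(m2, genome, codon = max(2L, floor(n_aa2 / 2)))
  m3 <- model_of("CAND03")
  n_aa3 <- (sum(m3$cds$end - m3$cds$start + 1L) / 3L) - 1L
  noncoseg <- pick_missense(m3, genome, codon = max(2L, floor(n_aa3 / 3)))

  # background biallelic SNVs
  nbg <- config$n_background_variants
  chrom_len <- nchar(genome[["chr1"]])
  forbidden <- c((ref$causal$run_start - 2L):(ref$causal$run_end + 2L),
                 anchor, decoy$pos + (-2L:2L), noncoseg$pos + (-2L:2L))
  avail <- setdiff(seq_len(chrom_len), forbidden)
  bg_pos <- sort(sample(avail, nbg))
  bg_ref <- vapply(bg_pos, function(p) genome_base(genome, "chr1", p), "")
  bg_alt <- vapply(bg_ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                   "", USE.NAMES = FALSE)
  bg_f <- stats::rbeta(nbg, config$af_beta[1], config$af_beta[2])

  samples <- c(case_id, control_ids)
  n_samp <- length(samples)
  gt <- matrix("0/0", nrow = nbg + 3L, ncol = n_samp,
               dimnames = list(NULL, samples))
  variants <- rbind(causal_rec,
                    data.frame(chrom = "chr1", pos = decoy$pos, ref = decoy$ref,
                               alt = decoy$alt, stringsAsFactors = FALSE),
                    data.frame(chrom = "chr1", pos = noncoseg$pos,
                               ref = noncoseg$ref, alt = noncoseg$alt,
                               stringsAsFactors = FALSE),
                    data.frame(chrom = "chr1", pos = bg_pos, ref = bg_ref,
                               alt = bg_alt, stringsAsFactors = FALSE))
  gt[1L, case_id] <- "1/1"              # causal: case homozygous
  gt[2L, case_id] <- "0/1"              # decoy missense: case het, private
  carrier_ctrls <- sample(control_ids, 2L)
  gt[3L, case_id] <- "0/1"              # non-cosegregating decoy
  gt[3L, carrier_ctrls] <- "0/1"        # carried by controls: not private
  for (i in seq_len(nbg)) {
    gt[3L + i, ] <- draw_hwe_gt(n_samp, bg_f[i])
  }
  # missingness: controls only; keep the planted decoy carriers observed
  miss <- matrix(stats::runif(nrow(gt) * length(control_ids)) <
                   config$missing_genotype_rate,
                 nrow = nrow(gt))
  miss[3L, match(carrier_ctrls, control_ids)] <- FALSE
  gtc <- gt[, control_ids, drop = FALSE]
  gtc[miss] <- "./."
  gt[, control_ids] <- gtc

  ord <- order(variants$pos)
  variants <- variants[ord, , drop = FALSE]; rownames(variants) <- NULL
  gt <- gt[ord, , drop = FALSE]
  cohort_cc <- cohort(variants, gt, genome = genome)

  # family genotypes at the causal and non-cosegregating sites
  fam_ids <- pedres$ped$id
  fam_gt <- matrix("0/0", nrow = 2L, ncol = length(fam_ids),
                   dimnames = list(NULL, fam_ids))
  fam_gt[1L, ] <- pedres$causal_gt[fam_ids]
  unaffected <- setdiff(fam_ids, affected)
  for (try in 1:200) {
    founder_gt <- stats::setNames(c("0/1", "1/1", "0/1", "0/1"),
                                  c("SIRE", "DAM1", "DAM2", "DAM3"))
    g <- founder_gt[fam_ids]
    names(g) <- fam_ids
    for (i in seq_len(nrow(pedres$ped))) {
      id <- pedres$ped$id[i]
      if (!is.na(pedres$ped$sire[i])) {
        a1 <- resample(transmissible(founder_gt[[pedres$ped$sire[i]]]), 1L)
        a2 <- resample(transmissible(founder_gt[[pedres$ped$dam[i]]]), 1L)
        g[[id]] <- c("0/0", "0/1", "1/1")[a1 + a2 + 1L]
      }
    }
    if (sum(g[unaffected] == "1/1") >= 1L) break
  }
  fam_gt[2L, ] <- g[fam_ids]
  fam_variants <- variants[variants$pos %in% c(anchor, noncoseg$pos), , drop = FALSE]
  fam_gt <- fam_gt[order(c(anchor, noncoseg$pos)), , drop = FALSE]
  family <- cohort(fam_variants, fam_gt, genome = genome)

  genotyping_controls <- data.frame(
    sample = sprintf("GTC%02d", seq_len(config$n_genotyping_controls)),
    genotype = "0/0", stringsAsFactors = FALSE)

  truth <- list(
    case_id = case_id, control_ids = control_ids,
    causal = list(gene = "CAND01", transcript = "tx-CAND01",
                  chrom = "chr1", pos = anchor, ref = anchor_base,
                  alt = paste0(anchor_base, "C"),
                  hgvs_genomic_dup_pos = ref$causal$run_end,
                  hgvs_c = "c.698dup", hgvs_p = "p.(Ser235Glnfs*4)",
                  run_start = ref$causal$run_start,
                  run_end = ref$causal$run_end),
    decoy_missense = decoy[c("chrom", "pos", "ref", "alt")],
    noncoseg = c(noncoseg[c("chrom", "pos", "ref", "alt")],
                 list(carrier_controls = carrier_ctrls)),
    background = data.frame(pos = bg_pos, ref = bg_ref, alt = bg_alt,
                            freq = bg_f, stringsAsFactors = FALSE))
  list(cohort = cohort_cc, family = family,
       genotyping_controls = genotyping_controls,
       case_id = case_id, control_ids = control_ids, truth = truth)
}

# ---- microsatellite markers -------------------------------------------------

#' Simulate a microsatellite marker panel over the pedigree
#'
#' Multi-allelic loci (4-10 alleles, alleles are integer repeat lengths);
#' founder genotypes drawn from the locus allele frequencies, non-founders by
#' Mendelian transmission. Deterministic given the seed.
#'
#' @param ped A [pedigree()].
#' @param n_loci Number of loci (default 16).
#' @param seed Integer seed.
#' @return List: `markers` (long data frame `sample`, `locus`, `allele1`,
#'   `allele2`), `loci` (list of per-locus allele/frequency tables).
#' @export
simulate_markers <- function(ped, n_loci = 16L, seed = 1L) {
  stopifnot(inherits(ped, "pedigree"))
  set.seed(seed)
  loci <- list()
  for (l in seq_len(n_loci)) {
    k <- sample(4:10, 1L)
    alleles <- sort(sample(seq(100L, 198L, by = 2L), k))
    w <- stats::runif(k) + 0.2
    loci[[sprintf("MS%02d", l)]] <- list(alleles = alleles, freq = w / sum(w))
  }
  # founders first so children can inherit
  ord <- order(!is.na(ped$sire) | !is.na(ped$dam))
  geno <- list()
  for (i in ord) {
    id <- ped$id[i]
    geno[[id]] <- lapply(loci, function(lc) {
      sort(sample(lc$alleles, 2L, replace = TRUE, prob = lc$freq))
    })
  }
  for (i in ord) {
    id <- ped$id[i]
    s <- ped$sire[i]; d <- ped$dam[i]
    if (is.na(s) && is.na(d)) next
    geno[[id]] <- lapply(stats::setNames(names(loci), names(loci)), function(ln) {
      from_s <- if (is.na(s)) sample(loci[[ln]]$alleles, 1L, prob = loci[[ln]]$freq)
                else resample(geno[[s]][[ln]], 1L)
      from_d <- if (is.na(d)) sample(loci[[ln]]$alleles, 1L, prob = loci[[ln]]$freq)
                else resample(geno[[d]][[ln]], 1L)
      sort(c(from_s, from_d))
    })
  }
  rows <- do.call(rbind, lapply(ped$id, function(id) {
    do.call(rbind, lapply(names(loci), function(ln) {
      data.frame(sample = id, locus = ln,
                 allele1 = geno[[id]][[ln]][1], allele2 = geno[[id]][[ln]][2],
                 stringsAsFactors = FALSE)
    }))
  }))
  list(markers = rows, loci = loci)
}

#' Draw a marker profile for an unrelated individual
#'
#' Sampled from the panel's locus allele frequencies with the current RNG
#' state (seed it with [set.seed()] for reproducibility).
#'
#' @param loci Locus table from [simulate_markers()].
#' @param id Sample id for the profile.
#' @return Long data frame in the marker-table format.
#' @export
simulate_unrelated_profile <- function(loci, id = "UNREL") {
  do.call(rbind, lapply(names(loci), function(ln) {
    a <- sort(sample(loci[[ln]]$alleles, 2L, replace = TRUE,
                     prob = loci[[ln]]$freq))
    data.frame(sample = id, locus = ln, allele1 = a[1], allele2 = a[2],
               stringsAsFactors = FALSE)
  }))
}

# ---- genotyping assay design ------------------------------------------------

#' Design genotyping primer pairs around a planted site
#'
#' Picks 20-mer primers producing a unique amplicon of the requested
#' reference length whose interior covers `region`. Exact-match in-silico PCR
#' verifies uniqueness.
#'
#' @param genome A [ref_genome()].
#' @param region Length-2 integer vector, genomic interval the amplicon
#'   interior must cover.
#' @param name Assay name.
#' @param product Reference product length in bp.
#' @return A [primer_pair()].
#' @export
design_primer_pair <- function(genome, region, name, product = 169L) {
  plen <- 20L
  for (shift in 0:60) {
    fstart <- region[1] - (product - (region[2] - region[1] + 1L)) %/% 2L + shift - plen
    if (fstart < 1L) next
    rend <- fstart + product - 1L
    if (rend > nchar(genome[["chr1"]])) break
    if (fstart + plen > region[1] || rend - plen < region[2]) next
    fwd <- genome_slice(genome, "chr1", fstart, fstart + plen - 1L)
    rev <- revcomp(genome_slice(genome, "chr1", rend - plen + 1L, rend))
    pp <- primer_pair(name, fwd, rev, max_product = 2000L)
    amp <- insilico_pcr(genome, pp)
    if (nrow(amp) == 1L && amp$length == product) return(pp)
  }
  stop("could not design a unique primer pair for ", name)
}

# ---- full cohort ------------------------------------------------------------

#' Generate the complete synthetic study cohort
#'
#' Runs [simulate_reference()], [simulate_pedigree()], [plant_variants()] and
#' [simulate_markers()] in that order (consuming seeds `seed`..`seed+3`),
#' designs the genotyping assays, and optionally writes every artifact to
#' `outdir` (FASTA, GFF3, VCFs, PED, marker/primer/control TSVs, candidate
#' and LOF gene lists, truth JSON). Identical config and seed give
#' byte-identical output files.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory.
#' @return List with all in-memory pieces: `genome`, `models`,
#'   `candidate_genes`, `lof_genes`, `ped`, `cohort`, `family`,
#'   `genotyping_controls`, `markers`, `loci`, `primers`, `case_id`,
#'   `control_ids`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config(), outdir = NULL) {
  ref <- simulate_reference(config)
  pedres <- simulate_pedigree(config)
  pv <- plant_variants(config, ref, pedres)
  mk <- simulate_markers(pedres$ped, n_loci = 16L, seed = config$seed + 3L)
  primers <- list(
    design_primer_pair(ref$genome,
                       c(ref$causal$run_start, ref$causal$run_end),
                       "CAND01-dup", product = 169L),
    design_primer_pair(ref$genome,
                       c(pv$truth$decoy_missense$pos, pv$truth$decoy_missense$pos),
                       "CAND02-snv", product = 152L))
  lof_genes <- c("CAND01", "CAND04", "CAND05")  # genes with known LOF mechanism
  out <- list(config = config, genome = ref$genome, models = ref$models,
              candidate_genes = ref$candidate_genes, lof_genes = lof_genes,
              ped = pedres$ped, causal_gt = pedres$causal_gt,
              cohort = pv$cohort, family = pv$family,
              genotyping_controls = pv$genotyping_controls,
              markers = mk$markers, loci = mk$loci, primers = primers,
              case_id = pv$case_id, control_ids = pv$control_ids,
              truth = pv$truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(outdir, f)
    write_fasta(out$genome, fp("reference.fa"))
    write_gff3(out$models, fp("genes.gff3"))
    write_vcf(out$cohort, fp("cohort.vcf"))
    write_vcf(out$family, fp("family.vcf"))
    write_ped(out$ped, fp("pedigree.ped"))
    writeLines(c("# functional candidate genes", out$candidate_genes),
               fp("candidate_genes.txt"))
    writeLines(c("# genes with an established loss-of-function mechanism",
                 out$lof_genes), fp("lof_genes.txt"))
    utils::write.table(out$markers, fp("markers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(out$genotyping_controls, fp("genotyping_controls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(name = vapply(primers, `[[`, "", "name"),
                 forward = vapply(primers, `[[`, "", "forward"),
                 reverse = vapply(primers, `[[`, "", "reverse"),
                 max_product = vapply(primers, function(p) p$max_product, 1L)),
      fp("primers.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out$truth, fp("truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  out
}
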