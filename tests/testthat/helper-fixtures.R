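# Shared fixtures. The default synthetic cohort (seed 1, study conditions)
# is expensive, so it is built once per test run and memoized.

fixture_env <- new.env(parent = emptyenv())

default_config <- function() sim_config(seed = 1L)

fixture_sim <- function() {
  if (is.null(fixture_env$sim)) {
    fixture_env$sim <- simulate_cohort(default_config())
  }
  fixture_env$sim
}

fixture_run <- function() {
  if (is.null(fixture_env$run)) {
    fixture_env$run <- run_all(default_config(), sim = fixture_sim(),
                               quiet = TRUE)
  }
  fixture_env$run
}

# single-exon plus-strand gene embedded in random flanks; returns the pieces
# needed by consequence tests
single_exon_gene <- function(cds, flank = 300L, gene = "TST", strand = "+") {
  genome_str <- paste0(random_dna(flank),
                       if (strand == "+") cds else revcomp(cds),
                       random_dna(flank))
  iv <- data.frame(start = flank + 1L, end = flank + nchar(cds))
  list(genome = ref_genome(c(chr1 = genome_str)),
       model = gene_model(gene, paste0("tx-", gene), "chr1", strand, iv),
       offset = flank)
}

trio_ped <- function() {
  pedigree(data.frame(id = c("S", "D", "K"),
                      sire = c(NA, NA, "S"), dam = c(NA, NA, "D"),
                      sex = c("male", "female", "male"),
                      affected = c("unaffected", "unaffected", "affected")))
}

write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# minimal VCF text for handmade records: rows = list of c(chrom,pos,ref,alt,gt...)
vcf_text <- function(samples, rows, format = "GT") {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(rows, function(r) {
      paste(c(r[1], r[2], ".", r[3], r[4], ".", ".", ".", format,
              r[-(1:4)]), collapse = "\t")
    }, character(1)))
}
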