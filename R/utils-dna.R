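# Small sequence helpers shared across modules. All sequences are plain
# uppercase character scalars over {A,C,G,T,N}; Biostrings does the actual
# biology (reverse complement, translation).

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a coding DNA string to one-letter amino acids
#'
#' Trailing bases that do not fill a codon are dropped (needed when
#' translating frameshifted sequence). Stop codons translate to `*`.
#'
#' @param s A single DNA string.
#' @return Single character string of one-letter amino-acid codes.
#' @export
translate_dna <- function(s) {
  n <- nchar(s)
  n3 <- n - n %% 3L
  if (n3 < 3L) return("")
  starts <- seq.int(1L, n3, 3L)
  aa <- unname(Biostrings::GENETIC_CODE[substring(s, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

# one-letter -> three-letter amino-acid code; stop is "*" (HGVS short form)
aa3 <- function(a) {
  code <- Biostrings::AMINO_ACID_CODE
  vapply(strsplit(a, "")[[1]], function(ch) {
    if (ch == "*") "*" else if (ch %in% names(code)) unname(code[ch]) else "Xaa"
  }, character(1), USE.NAMES = FALSE)
}

aa3_at <- function(protein, i) aa3(substr(protein, i, i))

is_dna <- function(x, allow_n = TRUE) {
  alph <- if (allow_n) "ACGTN" else "ACGT"
  grepl(paste0("^[", alph, "]+$"), x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() that never interprets a length-1 x as 1:x
resample <- function(x, n, ...) x[sample.int(length(x), n, ...)]
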