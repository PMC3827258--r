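# Standard genetic code, codon indexing, and small codon utilities shared by
# the alignment and substitution machinery.

NUCS <- c("T", "C", "A", "G")

# 64 codons in TCAG order; names are codons, values amino acids ('*' = stop).
.standardCode <- local({
  codons <- as.vector(outer(outer(NUCS, NUCS, paste0), NUCS, paste0))
  codons <- sort(codons)
  aa <- vapply(codons, function(cod) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(cod),
      genetic.code = Biostrings::GENETIC_CODE,
      no.init.codon = TRUE
    ))
  }, character(1))
  names(aa) <- codons
  aa
})

#' The standard genetic code as a named character vector
#'
#' @return Named character vector of length 64: names are codons (DNA
#'   alphabet, e.g. `"ATG"`), values are one-letter amino acids with `"*"`
#'   for the three stop codons.
#' @examples
#' standardGeneticCode()[["ATG"]]
#' @export
standardGeneticCode <- function() .standardCode

.isStopCodon <- function(codon) unname(.standardCode[codon] == "*")

senseCodons <- function() names(.standardCode)[.standardCode != "*"]

# Split a nucleotide string into codon triplets. No validation here.
.splitCodons <- function(x) {
  n <- nchar(x)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

.validCodon <- function(codon) {
  grepl("^[ACGT]{3}$", codon)
}

# All nine single-nucleotide neighbors of a codon (may include stops).
.codonNeighbors <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  out <- character(9L)
  k <- 0L
  for (pos in 1:3) {
    for (nt in NUCS[NUCS != chars[pos]]) {
      tmp <- chars
      tmp[pos] <- nt
      k <- k + 1L
      out[k] <- paste(tmp, collapse = "")
    }
  }
  out
}
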