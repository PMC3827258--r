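#' CodonAlignment: coding sequences in register with a protein alignment
#'
#' An S4 container for a nucleotide multiple alignment whose columns come in
#' codon triplets mirroring a protein alignment: every protein residue column
#' corresponds to one codon column-triple and every protein gap to `---`.
#' This is the substrate for all synonymous/non-synonymous substitution
#' statistics.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of equal-width aligned rows;
#'   width is a multiple of 3 and gaps occur only as whole-codon `---`.
#' @slot proteinSource Identifier of the protein alignment the object mirrors
#'   (free text, may be `""`).
#'
#' @seealso [backtranslateAlignment()] which constructs validated objects,
#'   [pairwiseDsDn()], [perCodonSd()].
#' @export
setClass("CodonAlignment",
  representation(sequences = "DNAStringSet", proteinSource = "character")
)

setValidity("CodonAlignment", function(object) {
  seqs <- object@sequences
  if (length(seqs) < 1L) return("alignment must contain at least one record")
  w <- unique(Biostrings::width(seqs))
  if (length(w) != 1L) return("all records must have the same aligned length")
  if (w == 0L) return("records must be non-empty")
  if (w %% 3L != 0L) return("aligned length must be a multiple of 3")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) return("all records must be named")
  if (anyDuplicated(ids)) {
    return(sprintf("duplicate record id: '%s'", ids[duplicated(ids)][1L]))
  }
  # gaps only in whole-codon triples
  for (i in seq_along(seqs)) {
    cods <- .splitCodons(as.character(seqs[[i]]))
    bad <- grepl("-", cods, fixed = TRUE) & cods != "---"
    if (any(bad)) {
      return(sprintf("record '%s': gap not spanning a whole codon at codon %d",
                     ids[i], which(bad)[1L]))
    }
  }
  TRUE
})

#' Construct a CodonAlignment from aligned coding sequences
#'
#' @param sequences A named [Biostrings::DNAStringSet] (or named character
#'   vector) of equal-length gapped coding sequences whose length is a
#'   multiple of 3 and whose gaps span whole codons.
#' @param proteinSource Optional identifier of the protein alignment the
#'   codon alignment mirrors.
#' @return A validated `CodonAlignment`.
#' @examples
#' CodonAlignment(c(a = "ATG---AAA", b = "ATGCTGAAA"))
#' @export
CodonAlignment <- function(sequences, proteinSource = "") {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  methods::new("CodonAlignment", sequences = sequences,
               proteinSource = as.character(proteinSource)[1L])
}

#' @describeIn CodonAlignment-class Number of aligned rows.
#' @param x A `CodonAlignment`.
#' @export
setMethod("length", "CodonAlignment", function(x) length(x@sequences))

#' Accessors for CodonAlignment
#'
#' `alignedSequences()` returns the underlying gapped [Biostrings::DNAStringSet];
#' `numCodons()` the number of codon columns; `seqIds()` the row identifiers.
#'
#' @param x A `CodonAlignment`.
#' @return See individual descriptions.
#' @export
alignedSequences <- function(x) {
  stopifnot(methods::is(x, "CodonAlignment"))
  x@sequences
}

#' @rdname alignedSequences
#' @export
numCodons <- function(x) {
  stopifnot(methods::is(x, "CodonAlignment"))
  Biostrings::width(x@sequences)[1L] %/% 3L
}

#' @rdname alignedSequences
#' @export
seqIds <- function(x) {
  stopifnot(methods::is(x, "CodonAlignment"))
  names(x@sequences)
}

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment with %d sequences x %d codons\n",
              length(object), numCodons(object)))
  if (nzchar(object@proteinSource)) {
    cat("  protein source:", object@proteinSource, "\n")
  }
  ids <- seqIds(object)
  shown <- utils::head(ids, 5L)
  cat("  ids:", paste(shown, collapse = ", "),
      if (length(ids) > 5L) sprintf("... (%d more)", length(ids) - 5L) else "",
      "\n")
})

# n x ncodon character matrix of codons; the workhorse layout for pairwise
# statistics.
codonMatrix <- function(x) {
  seqs <- as.character(alignedSequences(x))
  m <- vapply(seqs, .splitCodons, character(numCodons(x)))
  # vapply drops to a vector for single-codon alignments
  m <- matrix(m, nrow = numCodons(x), dimnames = list(NULL, names(seqs)))
  t(m)
}
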