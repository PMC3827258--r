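# FASTA input/output and codon-alignment construction: reading validated
# sequence sets, CDS translation, and back-translation of a protein
# alignment onto unaligned coding sequences.

.ALPHABETS <- list(
  nucleotide = "ACGTN-",
  protein    = "ACDEFGHIKLMNPQRSTVWYX-"
)

#' Read a FASTA file into a validated string set
#'
#' Reads FASTA, uppercases residues, and validates identifiers and alphabet.
#' The first whitespace-delimited token of each header is the record id; the
#' remainder is kept as the record description.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` (ACGTN and `-`) or `"protein"` (20 amino
#'   acids, X and `-`).
#' @return A [Biostrings::DNAStringSet] (nucleotide) or
#'   [Biostrings::AAStringSet] (protein), names set to record ids and a
#'   `description` entry in `metadata()`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "atg", ">b", "TTT"), fa)
#' readFasta(fa, "nucleotide")
#' @export
readFasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  .assertFileExists(path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop(sprintf("empty FASTA file: '%s'", path), call. = FALSE)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("FASTA record with empty id", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA id: '%s'", ids[duplicated(ids)][1L]), call. = FALSE)
  }
  seqs <- toupper(gsub("[ \t\r]", "", as.character(raw)))
  if (any(!nzchar(seqs))) {
    stop(sprintf("empty sequence for record '%s'", ids[which(!nzchar(seqs))[1L]]),
         call. = FALSE)
  }
  allowed <- .ALPHABETS[[alphabet]]
  bad <- regexpr(sprintf("[^%s]", allowed), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf(
      "record '%s': character '%s' at position %d outside %s alphabet",
      ids[i], substr(seqs[i], bad[i], bad[i]), bad[i], alphabet), call. = FALSE)
  }
  out <- if (alphabet == "nucleotide") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::metadata(out)$description <- stats::setNames(desc, ids)
  out
}

#' Write a string set to FASTA
#'
#' @param x A named `XStringSet` (or `CodonAlignment`, whose aligned rows are
#'   written).
#' @param path Output file path.
#' @param width Line width for sequence lines (default 60).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 60L) {
  if (methods::is(x, "CodonAlignment")) x <- alignedSequences(x)
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}

#' Translate a coding sequence
#'
#' Translates an ungapped CDS under the standard genetic code. A single
#' terminal stop codon is stripped and flagged; internal stop codons are
#' errors. Codons containing `N` are either errors (default) or translated
#' to `X`.
#'
#' @param cds A nucleotide string (or `DNAString`), length a multiple of 3.
#' @param ambiguous `"error"` to reject codons containing N, `"X"` to
#'   translate them as X.
#' @return A list with `protein` (character) and `terminalStop` (logical).
#' @examples
#' translateCds("ATGTAA")  # $protein "M", $terminalStop TRUE
#' @export
translateCds <- function(cds, ambiguous = c("error", "X")) {
  ambiguous <- match.arg(ambiguous)
  cds <- toupper(as.character(cds))
  if (nchar(cds) == 0L) stop("empty CDS", call. = FALSE)
  if (nchar(cds) %% 3L != 0L) {
    stop(sprintf("CDS length %d is not a multiple of 3", nchar(cds)), call. = FALSE)
  }
  codons <- .splitCodons(cds)
  aa <- character(length(codons))
  code <- standardGeneticCode()
  for (i in seq_along(codons)) {
    cod <- codons[i]
    if (!.validCodon(cod)) {
      if (grepl("N", cod, fixed = TRUE) && grepl("^[ACGTN]{3}$", cod)) {
        if (ambiguous == "error") {
          stop(sprintf("ambiguous codon '%s' at codon %d", cod, i), call. = FALSE)
        }
        aa[i] <- "X"
        next
      }
      stop(sprintf("invalid codon '%s' at codon %d", cod, i), call. = FALSE)
    }
    aa[i] <- code[[cod]]
  }
  terminalStop <- FALSE
  n <- length(aa)
  if (n > 0L && aa[n] == "*") {
    terminalStop <- TRUE
    aa <- aa[-n]
  }
  if (any(aa == "*")) {
    stop(sprintf("internal stop codon at codon %d", which(aa == "*")[1L]),
         call. = FALSE)
  }
  list(protein = paste(aa, collapse = ""), terminalStop = terminalStop)
}

#' Back-translate a protein alignment onto coding sequences
#'
#' Threads each unaligned CDS through its row of a protein multiple
#' alignment: every residue column expands to the corresponding codon and
#' every gap to `---`, producing a codon alignment in register with the
#' protein alignment. Each ungapped CDS (after stripping a terminal stop)
#' must translate exactly to its ungapped protein row.
#'
#' @param proteinAln A named [Biostrings::AAStringSet] of equal-width gapped
#'   protein rows (or named character vector).
#' @param cdsSet A named [Biostrings::DNAStringSet] (or named character
#'   vector) of unaligned coding sequences; every protein row id must be
#'   present.
#' @param dropColumns Optional integer vector of 1-based protein alignment
#'   columns to remove before expansion, applied identically to protein and
#'   codon alignment (explicit removal of unreliably aligned columns is the
#'   caller's decision).
#' @param proteinSource Identifier stored on the result.
#' @return A [CodonAlignment-class] object.
#' @examples
#' backtranslateAlignment(c(a = "M-K", b = "MLK"),
#'                        c(a = "ATGAAA", b = "ATGCTGAAA"))
#' @export
backtranslateAlignment <- function(proteinAln, cdsSet, dropColumns = NULL,
                                   proteinSource = "") {
  if (is.character(proteinAln)) proteinAln <- Biostrings::AAStringSet(proteinAln)
  if (is.character(cdsSet)) cdsSet <- Biostrings::DNAStringSet(cdsSet)
  ids <- names(proteinAln)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("protein alignment rows must have unique names", call. = FALSE)
  }
  w <- unique(Biostrings::width(proteinAln))
  if (length(w) != 1L) stop("protein alignment rows differ in length", call. = FALSE)
  missing <- setdiff(ids, names(cdsSet))
  if (length(missing)) {
    stop(sprintf("no CDS for alignment row(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(dropColumns)) {
    dropColumns <- as.integer(dropColumns)
    if (any(dropColumns < 1L | dropColumns > w)) {
      stop("dropColumns outside alignment", call. = FALSE)
    }
  }
  out <- character(length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    prow <- strsplit(as.character(proteinAln[[k]]), "")[[1]]
    if (!is.null(dropColumns)) prow <- prow[-dropColumns]
    ungapped <- prow[prow != "-"]
    cds <- as.character(cdsSet[[id]])
    tr <- translateCds(cds)
    if (tr$terminalStop) cds <- substr(cds, 1L, nchar(cds) - 3L)
    prot <- strsplit(tr$protein, "")[[1]]
    target <- if (is.null(dropColumns)) ungapped else {
      # with columns dropped the CDS still covers the full row: align codons
      # to the *undropped* residues by position in the original row
      NULL
    }
    if (is.null(dropColumns)) {
      if (length(prot) != length(ungapped) || any(prot != ungapped)) {
        n <- min(length(prot), length(ungapped))
        mism <- which(prot[seq_len(n)] != ungapped[seq_len(n)])
        at <- if (length(mism)) mism[1L] else n + 1L
        stop(sprintf(
          "row '%s': CDS translation does not match protein row (first mismatch at residue %d)",
          id, at), call. = FALSE)
      }
      codons <- .splitCodons(cds)
      expanded <- character(length(prow))
      expanded[prow == "-"] <- "---"
      expanded[prow != "-"] <- codons
      out[k] <- paste(expanded, collapse = "")
    } else {
      # re-run against the full (undropped) row, then drop codon triples
      full <- strsplit(as.character(proteinAln[[k]]), "")[[1]]
      ungappedFull <- full[full != "-"]
      if (length(prot) != length(ungappedFull) || any(prot != ungappedFull)) {
        n <- min(length(prot), length(ungappedFull))
        mism <- which(prot[seq_len(n)] != ungappedFull[seq_len(n)])
        at <- if (length(mism)) mism[1L] else n + 1L
        stop(sprintf(
          "row '%s': CDS translation does not match protein row (first mismatch at residue %d)",
          id, at), call. = FALSE)
      }
      codons <- .splitCodons(cds)
      expanded <- character(length(full))
      expanded[full == "-"] <- "---"
      expanded[full != "-"] <- codons
      out[k] <- paste(expanded[-dropColumns], collapse = "")
    }
  }
  names(out) <- ids
  CodonAlignment(out, proteinSource = proteinSource)
}

#' Drop alignment columns explicitly
#'
#' Removes an explicit set of columns from a protein alignment, or the
#' corresponding codon column-triples from a [CodonAlignment-class]. There is
#' deliberately no automated column-quality filter: which columns are
#' unreliably aligned is the caller's decision.
#'
#' @param x An `AAStringSet` (protein alignment) or `CodonAlignment`.
#' @param columns 1-based protein-column indices to remove. For a
#'   `CodonAlignment` these index codon columns.
#' @return Object of the same class with the columns removed.
#' @export
dropAlignmentColumns <- function(x, columns) {
  columns <- sort(unique(as.integer(columns)))
  if (methods::is(x, "CodonAlignment")) {
    nc <- numCodons(x)
    if (any(columns < 1L | columns > nc)) stop("columns outside alignment", call. = FALSE)
    keepNt <- setdiff(seq_len(3L * nc),
                      as.vector(vapply(columns, function(j) (3L * (j - 1L)) + 1:3,
                                       integer(3))))
    seqs <- as.character(alignedSequences(x))
    trimmed <- vapply(seqs, function(s) {
      paste(strsplit(s, "")[[1]][keepNt], collapse = "")
    }, character(1))
    return(CodonAlignment(trimmed, proteinSource = x@proteinSource))
  }
  w <- unique(Biostrings::width(x))
  if (length(w) != 1L) stop("alignment rows differ in length", call. = FALSE)
  if (any(columns < 1L | columns > w)) stop("columns outside alignment", call. = FALSE)
  keep <- setdiff(seq_len(w), columns)
  mat <- as.matrix(x)[, keep, drop = FALSE]
  out <- Biostrings::AAStringSet(apply(mat, 1L, paste, collapse = ""))
  names(out) <- names(x)
  out
}
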