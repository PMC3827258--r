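# Independent oracles and fixture builders used across the suite. These are
# deliberately written as naive re-derivations (separate code paths from the
# package internals) so they can arbitrate correctness.

# genetic code for the oracles, taken straight from Biostrings
oracleCode <- as.list(Biostrings::GENETIC_CODE)
names(oracleCode) <- gsub("U", "T", names(Biostrings::GENETIC_CODE))

oracleTranslate <- function(codon) oracleCode[[codon]]

# all orderings of up to three positions, written out longhand
oraclePerms <- function(v) {
  d <- length(v)
  if (d == 1L) return(list(v))
  if (d == 2L) return(list(v, rev(v)))
  list(c(v[1], v[2], v[3]), c(v[1], v[3], v[2]),
       c(v[2], v[1], v[3]), c(v[2], v[3], v[1]),
       c(v[3], v[1], v[2]), c(v[3], v[2], v[1]))
}

# exhaustive-permutation pathway counting: average synonymous /
# non-synonymous step counts over minimal pathways, skipping pathways that
# visit a stop codon (averaging over all pathways if none survives)
oraclePathwayCounts <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  diffs <- which(ca != cb)
  if (length(diffs) == 0L) return(c(Sd = 0, Nd = 0))
  all <- list()
  for (ord in oraclePerms(diffs)) {
    cur <- ca
    sd <- 0
    nd <- 0
    stopHit <- FALSE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- cb[p]
      if (oracleTranslate(paste(nxt, collapse = "")) == "*") stopHit <- TRUE
      if (oracleTranslate(paste(cur, collapse = "")) ==
          oracleTranslate(paste(nxt, collapse = ""))) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    all[[length(all) + 1L]] <- c(sd, nd, stopHit)
  }
  m <- do.call(rbind, all)
  keep <- m[m[, 3] == 0, , drop = FALSE]
  if (nrow(keep) == 0L) keep <- m
  c(Sd = mean(keep[, 1]), Nd = mean(keep[, 2]))
}

# naive per-position site fractions for one codon
oracleCodonSites <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  aa <- oracleTranslate(codon)
  total <- 0
  for (pos in 1:3) {
    syn <- 0
    nonstop <- 0
    for (nt in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      mut <- chars
      mut[pos] <- nt
      maa <- oracleTranslate(paste(mut, collapse = ""))
      if (maa == "*") next
      nonstop <- nonstop + 1
      if (maa == aa) syn <- syn + 1
    }
    if (nonstop > 0) total <- total + syn / nonstop
  }
  total
}

# naive modal-residue percent identity (denominator = all rows)
oracleColumnConsensus <- function(residues) {
  counts <- integer(0)
  for (r in residues) {
    if (r == "-") next
    counts[r] <- if (is.na(counts[r])) 1L else counts[r] + 1L
  }
  if (length(counts) == 0L) return(list(res = NA_character_, pid = 0))
  best <- names(counts)[order(-counts, names(counts))][1L]
  list(res = best, pid = 100 * max(counts) / length(residues))
}

# naive type-7 quantile: h = (n-1) p + 1, linear interpolation
oracleQuantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# fixture: small codon alignment built from explicit codon vectors
makeCodonAln <- function(...) {
  rows <- list(...)
  seqs <- vapply(rows, paste, character(1), collapse = "")
  names(seqs) <- paste0("seq", seq_along(seqs))
  CodonAlignment(seqs)
}

# fixture: annotation table with one 25-gene contig
makeContigFeatures <- function(n = 25L, genome = "g1", contig = "c1") {
  starts <- seq_len(n) * 1000L
  data.frame(
    genome_id = genome, contig_id = contig,
    locus_tag = sprintf("%s_%03d", genome, seq_len(n)),
    gene_name = sprintf("gene%03d", seq_len(n)),
    start = starts, end = starts + 800L,
    strand = rep(c("+", "-"), length.out = n),
    product = "hypothetical protein", stringsAsFactors = FALSE
  )
}
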