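# Synonymous/non-synonymous substitution statistics on codon alignments:
# Nei-Gojobori site fractions, pathway-averaged difference counting,
# Jukes-Cantor correction with a saturation guard, pairwise dS/dN and
# per-codon synonymous-substitution profiles.

# --- site counting -----------------------------------------------------------

#' Synonymous and non-synonymous site counts of a codon
#'
#' For each codon position the synonymous fraction is the number of
#' synonymous single-nucleotide neighbors divided by the number of non-stop
#' single-nucleotide neighbors (mutations to stop codons are excluded from
#' the denominator). `sSites` is the sum of the three fractions and
#' `nSites = 3 - sSites`.
#'
#' @param codon A sense codon (DNA alphabet, e.g. `"TTT"`).
#' @return A list with `codon`, `sSites` and `nSites`.
#' @examples
#' codonSites("TTT")$sSites  # 1/3
#' codonSites("GGG")$sSites  # 1
#' @export
codonSites <- function(codon) {
  codon <- toupper(as.character(codon))
  if (!.validCodon(codon)) {
    stop(sprintf("invalid codon '%s' (gap or ambiguity codons must be skipped by the caller)",
                 codon), call. = FALSE)
  }
  if (.isStopCodon(codon)) {
    stop(sprintf("stop codon '%s' has no site counts", codon), call. = FALSE)
  }
  code <- standardGeneticCode()
  aa <- code[[codon]]
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L
    nonstop <- 0L
    for (nt in NUCS[NUCS != chars[pos]]) {
      tmp <- chars
      tmp[pos] <- nt
      neigh <- paste(tmp, collapse = "")
      if (code[[neigh]] == "*") next
      nonstop <- nonstop + 1L
      if (code[[neigh]] == aa) syn <- syn + 1L
    }
    if (nonstop > 0L) s <- s + syn / nonstop
  }
  list(codon = codon, sSites = s, nSites = 3 - s)
}

# cache of per-codon site counts and pathway matrices, filled lazily
.subCache <- new.env(parent = emptyenv())

.siteTable <- function() {
  if (is.null(.subCache$sites)) {
    sense <- senseCodons()
    s <- vapply(sense, function(cod) codonSites(cod)$sSites, numeric(1))
    full <- stats::setNames(rep(NA_real_, 64L), names(standardGeneticCode()))
    full[sense] <- s
    .subCache$sites <- full
  }
  .subCache$sites
}

# --- pathway counting --------------------------------------------------------

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Classify one pathway (ordering of differing positions): returns
# c(sd, nd, hitsStop). Steps are synonymous iff the encoded amino acid is
# unchanged; a step onto a stop codon marks the pathway as stop-traversing.
.walkPathway <- function(fromChars, toChars, order, code) {
  cur <- fromChars
  sd <- 0
  nd <- 0
  hitsStop <- FALSE
  for (pos in order) {
    nxt <- cur
    nxt[pos] <- toChars[pos]
    aaCur <- code[[paste(cur, collapse = "")]]
    aaNxt <- code[[paste(nxt, collapse = "")]]
    if (aaNxt == "*") hitsStop <- TRUE
    if (aaCur == aaNxt) sd <- sd + 1 else nd <- nd + 1
    cur <- nxt
  }
  c(sd, nd, as.numeric(hitsStop))
}

#' Pathway-averaged synonymous/non-synonymous differences between two codons
#'
#' Enumerates all minimal mutational pathways between two sense codons (d!
#' orderings for d differing positions), classifies each single-nucleotide
#' step as synonymous or non-synonymous, and averages the step counts over
#' pathways. Pathways passing through a stop codon are excluded; if every
#' pathway does, the average is taken over all pathways instead. `Sd + Nd`
#' always equals the number of differing positions.
#'
#' @param codonA,codonB Sense codons.
#' @return Numeric vector `c(Sd = ..., Nd = ...)`.
#' @examples
#' pathwayCounts("GGG", "GGA")  # c(Sd = 1, Nd = 0)
#' pathwayCounts("TTT", "GTA")  # c(Sd = 0.5, Nd = 1.5)
#' @export
pathwayCounts <- function(codonA, codonB) {
  codonA <- toupper(as.character(codonA))
  codonB <- toupper(as.character(codonB))
  for (cod in c(codonA, codonB)) {
    if (!.validCodon(cod)) stop(sprintf("invalid codon '%s'", cod), call. = FALSE)
    if (.isStopCodon(cod)) stop(sprintf("stop codon '%s'", cod), call. = FALSE)
  }
  m <- .pathwayMatrices()
  c(Sd = m$Sd[codonA, codonB], Nd = m$Nd[codonA, codonB])
}

# 64x64 Sd/Nd lookup matrices over sense-codon pairs (NA on stop rows/cols).
.pathwayMatrices <- function() {
  if (!is.null(.subCache$pathSd)) {
    return(list(Sd = .subCache$pathSd, Nd = .subCache$pathNd))
  }
  code <- standardGeneticCode()
  codons <- names(code)
  n <- length(codons)
  Sd <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  Nd <- Sd
  sense <- senseCodons()
  charList <- strsplit(codons, "")
  names(charList) <- codons
  for (a in sense) {
    for (b in sense) {
      if (a == b) {
        Sd[a, b] <- 0
        Nd[a, b] <- 0
        next
      }
      if (!is.na(Sd[b, a])) {  # symmetry
        Sd[a, b] <- Sd[b, a]
        Nd[a, b] <- Nd[b, a]
        next
      }
      fa <- charList[[a]]
      fb <- charList[[b]]
      diffPos <- which(fa != fb)
      paths <- .permutations(diffPos)
      res <- vapply(paths, function(ord) .walkPathway(fa, fb, ord, code),
                    numeric(3))
      ok <- res[3, ] == 0
      use <- if (any(ok)) res[, ok, drop = FALSE] else res
      Sd[a, b] <- mean(use[1, ])
      Nd[a, b] <- mean(use[2, ])
    }
  }
  .subCache$pathSd <- Sd
  .subCache$pathNd <- Nd
  list(Sd = Sd, Nd = Nd)
}

# --- Jukes-Cantor ------------------------------------------------------------

#' Jukes-Cantor correction of a difference proportion
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`. The transformation is only defined for
#' `p < 0.75`: at `p >= 0.75` the logarithm's argument is non-positive and
#' `NA` is returned (the saturation guard). Vectorised over `p`.
#'
#' @param p Proportion(s) of differences, `p >= 0`.
#' @return Corrected distance(s); `NA` where saturated.
#' @examples
#' jukesCantor(c(0, 0.5, 0.75))
#' @export
jukesCantor <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric", call. = FALSE)
  if (any(p < 0, na.rm = TRUE)) stop("negative proportion", call. = FALSE)
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - (4 / 3) * p[ok])
  out
}

# --- pairwise statistics -----------------------------------------------------

# codon matrix rows -> 1..64 indices into the code table; NA for gap,
# ambiguity, or stop codons (non-comparable).
.codonIndexMatrix <- function(cmat) {
  codons <- names(standardGeneticCode())
  idx <- match(cmat, codons)
  dim(idx) <- dim(cmat)
  stopIdx <- which(standardGeneticCode() == "*")
  idx[idx %in% stopIdx] <- NA_integer_
  idx
}

# core pairwise computation on two index vectors
.pairStats <- function(ia, ib, idA, idB) {
  ok <- !is.na(ia) & !is.na(ib)
  nc <- sum(ok)
  if (nc < 1L) {
    stop(sprintf("no comparable codons between '%s' and '%s'", idA, idB),
         call. = FALSE)
  }
  sites <- .siteTable()
  m <- .pathwayMatrices()
  sA <- sum(sites[ia[ok]])
  sB <- sum(sites[ib[ok]])
  S <- (sA + sB) / 2
  N <- 3 * nc - S
  cells <- cbind(ia[ok], ib[ok])
  Sd <- sum(m$Sd[cells])
  Nd <- sum(m$Nd[cells])
  # a pair can have zero synonymous (or non-synonymous) opportunity, e.g.
  # poly-Met rows; with no sites and no differences the proportion is 0
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- jukesCantor(pS)
  dN <- jukesCantor(pN)
  saturated <- (pS >= 0.75) || (pN >= 0.75)
  if (saturated) {
    ratio <- NA_real_
    reason <- "saturated"
  } else if (dN > 0) {
    ratio <- dS / dN
    reason <- ""
  } else {
    ratio <- NA_real_
    reason <- "dN_zero"
  }
  data.frame(
    id_a = idA, id_b = idB, codons_compared = nc,
    S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    dS = dS, dN = dN, ratio = ratio,
    saturated = saturated, computable = !is.na(ratio), reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Pairwise dS/dN between two rows of a codon alignment
#'
#' Codon positions where either row carries a gap, an ambiguity, or a stop
#' codon are skipped, so each pair is compared over its maximal comparable
#' codon set. Site counts `S` and `N` are the means of the two rows' summed
#' per-codon site fractions; `Sd` and `Nd` are summed pathway-averaged
#' difference counts; `pS = Sd/S` and `pN = Nd/N` are Jukes-Cantor corrected
#' into `dS` and `dN`. The ratio `dS/dN` is reported only when both distances
#' are defined and `dN > 0`; pairs with `pS >= 0.75` or `pN >= 0.75` are
#' flagged `saturated` and their ratio is missing.
#'
#' @param aln A [CodonAlignment-class].
#' @param a,b Row identifiers (or 1-based row indices).
#' @return One-row `data.frame` with columns `id_a`, `id_b`,
#'   `codons_compared`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`,
#'   `ratio`, `saturated`, `computable`, `reason`.
#' @seealso [allPairsDsDn()] for every pair, [perSequenceMeanDsDn()] for
#'   per-sequence means.
#' @export
pairwiseDsDn <- function(aln, a, b) {
  stopifnot(methods::is(aln, "CodonAlignment"))
  ids <- seqIds(aln)
  resolve <- function(x) {
    if (is.numeric(x)) return(ids[as.integer(x)])
    if (!x %in% ids) stop(sprintf("unknown sequence id '%s'", x), call. = FALSE)
    x
  }
  a <- resolve(a)
  b <- resolve(b)
  idx <- .codonIndexMatrix(codonMatrix(aln))
  .pairStats(idx[match(a, ids), ], idx[match(b, ids), ], a, b)
}

#' All pairwise dS/dN comparisons of a codon alignment
#'
#' @param aln A [CodonAlignment-class] with at least 2 rows.
#' @return A `data.frame` with one row per unordered pair, columns as in
#'   [pairwiseDsDn()].
#' @export
allPairsDsDn <- function(aln) {
  stopifnot(methods::is(aln, "CodonAlignment"))
  n <- length(aln)
  if (n < 2L) stop("at least 2 sequences required", call. = FALSE)
  ids <- seqIds(aln)
  idx <- .codonIndexMatrix(codonMatrix(aln))
  rows <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      k <- k + 1L
      rows[[k]] <- .pairStats(idx[i, ], idx[j, ], ids[i], ids[j])
    }
  }
  do.call(rbind, rows)
}

#' Per-sequence mean dS/dN over computable pairs
#'
#' For each sequence, the mean of the pairwise `dS/dN` ratio over all pairs
#' involving it that are computable (unsaturated, `dN > 0`). Saturated or
#' otherwise non-computable pairs count toward `pairs_total` only.
#'
#' @param aln A [CodonAlignment-class] with at least 2 rows, or a
#'   `data.frame` produced by [allPairsDsDn()].
#' @return A list with `perSequence` (a `data.frame` with `id`, `mean_ratio`,
#'   `pairs_computable`, `pairs_total`) and `computableFraction`, the global
#'   fraction of pairs with a defined ratio.
#' @export
perSequenceMeanDsDn <- function(aln) {
  pairs <- if (is.data.frame(aln)) aln else allPairsDsDn(aln)
  ids <- unique(c(pairs$id_a, pairs$id_b))
  per <- lapply(ids, function(id) {
    mine <- pairs[pairs$id_a == id | pairs$id_b == id, , drop = FALSE]
    comp <- mine[mine$computable, , drop = FALSE]
    data.frame(
      id = id,
      mean_ratio = if (nrow(comp)) mean(comp$ratio) else NA_real_,
      pairs_computable = nrow(comp),
      pairs_total = nrow(mine),
      stringsAsFactors = FALSE
    )
  })
  list(
    perSequence = do.call(rbind, per),
    computableFraction = mean(pairs$computable)
  )
}

#' Per-codon mean synonymous substitution profile
#'
#' For every codon column, the mean over all sequence pairs (both codons
#' comparable: no gap, ambiguity or stop) of the pathway-averaged synonymous
#' difference count `Sd` at that codon.
#'
#' @param aln A [CodonAlignment-class] with at least 2 rows.
#' @return A `data.frame` with `codon_index` (1-based), `mean_Sd` (`NA` when
#'   no pair is comparable) and `pairs_used`.
#' @export
perCodonSd <- function(aln) {
  stopifnot(methods::is(aln, "CodonAlignment"))
  n <- length(aln)
  if (n < 2L) stop("at least 2 sequences required", call. = FALSE)
  idx <- .codonIndexMatrix(codonMatrix(aln))
  m <- .pathwayMatrices()
  ncod <- numCodons(aln)
  sums <- numeric(ncod)
  used <- integer(ncod)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
      sd <- m$Sd[cbind(idx[i, ok], idx[j, ok])]
      sums[ok] <- sums[ok] + sd
      used[ok] <- used[ok] + 1L
    }
  }
  data.frame(
    codon_index = seq_len(ncod),
    mean_Sd = ifelse(used > 0L, sums / pmax(used, 1L), NA_real_),
    pairs_used = used
  )
}
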