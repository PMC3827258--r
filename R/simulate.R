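# Synthetic-data generators: codon alignments evolved at a controlled dN/dS
# along a tree, annotation tables with planted neighborhood gene
# frequencies, and multi-spanning membrane proteins with known TM
# intervals. Each generator draws from its own stream derived from the
# master seed, so adding one simulation does not perturb the others.

.GENERATOR_STREAM <- c(alignment = 1L, operon = 2L, tm = 3L)

.generatorSeed <- function(seed, which) {
  splitSeed(as.integer(seed), 3L)[[.GENERATOR_STREAM[[which]]]]
}

#' Star tree constructor
#'
#' @param nLeaves Number of leaves.
#' @param branchLength Branch length from the root to every leaf, in
#'   expected substitution events per codon (pre-selection).
#' @return An [ape::read.tree] `phylo` object with tips `t1..tn`.
#' @export
starTree <- function(nLeaves, branchLength) {
  tips <- paste0("t", seq_len(nLeaves))
  nwk <- sprintf("(%s);",
                 paste(sprintf("%s:%g", tips, branchLength), collapse = ","))
  ape::read.tree(text = nwk)
}

#' Simulate a codon alignment evolved at a controlled dN/dS
#'
#' Evolves a stop-free codon sequence along a rooted tree with branch
#' lengths in expected substitution events per codon (pre-selection). Along
#' each branch, each codon receives a Poisson number of proposal events with
#' mean equal to the branch length; each proposal is a uniform
#' single-nucleotide change, proposals creating stop codons are rejected,
#' and selection acts through acceptance probabilities `min(1, omega)` for
#' non-synonymous and `min(1, 1/omega)` for synonymous proposals, so the
#' realized non-synonymous:synonymous rate ratio per opportunity equals
#' `omega`. All accepted events are logged per branch.
#'
#' @param tree A `phylo` object with branch lengths, or a Newick string.
#' @param nCodons Number of codons (ignored when `rootSequence` is given).
#' @param omega Target dN/dS (> 0).
#' @param seed Integer master seed (the alignment generator uses its own
#'   stream derived from it).
#' @param rootSequence Optional stop-free codon string to start from.
#' @return A list of class `SimulatedAlignment` with `alignment` (an
#'   ungapped [CodonAlignment-class] over the tips), `config` (the
#'   generating parameters), and `eventLog` (`data.frame` of per-branch
#'   accepted synonymous / non-synonymous event counts).
#' @export
simulateCodonAlignment <- function(tree, nCodons = 300L, omega = 1,
                                   seed = 1L, rootSequence = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  .assertScalarNumber(omega, "omega")
  if (omega <= 0) stop("omega must be > 0", call. = FALSE)
  code <- standardGeneticCode()
  sense <- senseCodons()
  withSeed(.generatorSeed(seed, "alignment"), {
    if (is.null(rootSequence)) {
      rootCodons <- sample(sense, nCodons, replace = TRUE)
    } else {
      rootCodons <- .splitCodons(toupper(rootSequence))
      if (any(!rootCodons %in% sense)) {
        stop("rootSequence must consist of sense codons", call. = FALSE)
      }
      nCodons <- length(rootCodons)
    }
    pAccSyn <- min(1, 1 / omega)
    pAccNon <- min(1, omega)
    evolveBranch <- function(codons, t) {
      nSyn <- 0L
      nNon <- 0L
      if (t > 0) {
        nEv <- stats::rpois(length(codons), t)
        for (i in which(nEv > 0L)) {
          for (e in seq_len(nEv[i])) {
            chars <- strsplit(codons[i], "")[[1]]
            pos <- sample.int(3L, 1L)
            nt <- sample(NUCS[NUCS != chars[pos]], 1L)
            chars[pos] <- nt
            prop <- paste(chars, collapse = "")
            if (code[[prop]] == "*") next
            syn <- code[[prop]] == code[[codons[i]]]
            pAcc <- if (syn) pAccSyn else pAccNon
            if (stats::runif(1) <= pAcc) {
              codons[i] <- prop
              if (syn) nSyn <- nSyn + 1L else nNon <- nNon + 1L
            }
          }
        }
      }
      list(codons = codons, syn = nSyn, nonsyn = nNon)
    }
    nTips <- length(tree$tip.label)
    root <- nTips + 1L
    seqsAt <- vector("list", nTips + tree$Nnode)
    seqsAt[[root]] <- rootCodons
    logRows <- vector("list", nrow(tree$edge))
    # preorder traversal: parents always appear before children in reorder()
    ord <- stats::reorder(tree, "cladewise")
    for (k in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[k, 1L]
      child <- ord$edge[k, 2L]
      res <- evolveBranch(seqsAt[[parent]], ord$edge.length[k])
      seqsAt[[child]] <- res$codons
      logRows[[k]] <- data.frame(parent = parent, child = child,
                                 branch_length = ord$edge.length[k],
                                 syn_events = res$syn,
                                 nonsyn_events = res$nonsyn)
    }
    leafSeqs <- vapply(seq_len(nTips), function(i) {
      paste(seqsAt[[i]], collapse = "")
    }, character(1))
    names(leafSeqs) <- tree$tip.label
  })
  structure(list(
    alignment = CodonAlignment(leafSeqs, proteinSource = "simulated"),
    config = list(nCodons = nCodons, omega = omega, seed = seed,
                  tree = ape::write.tree(tree)),
    eventLog = do.call(rbind, logRows)
  ), class = "SimulatedAlignment")
}

#' Simulate annotation tables with planted neighborhood gene frequencies
#'
#' Generates, for each genome, one contig carrying a focal locus flanked by
#' `window` gene slots on each side. Each planted gene appears in the
#' neighborhood independently with its configured probability, at a
#' randomized free slot and strand; remaining slots are padded with filler
#' genes bearing unique names.
#'
#' @param nGenomes Number of genomes (>= 1).
#' @param plantedFreqs Named numeric vector: gene name -> presence
#'   probability in `[0, 1]`.
#' @param window Gene slots per side of the focal locus (default 10).
#' @param seed Integer master seed (operon generator stream).
#' @return A list of class `SimulatedOperonSet` with `features` (annotation
#'   `data.frame` in [readFeatures()] output schema), `focalLoci` (one locus
#'   tag per genome), `truth` (the planted probabilities) and `window`.
#' @export
simulateOperonTables <- function(nGenomes = 50L, plantedFreqs = c(tata = 0.8),
                                 window = 10L, seed = 1L) {
  nGenomes <- as.integer(nGenomes)
  if (nGenomes < 1L) stop("nGenomes must be >= 1", call. = FALSE)
  if (any(plantedFreqs < 0 | plantedFreqs > 1)) {
    stop("planted probabilities must be in [0, 1]", call. = FALSE)
  }
  window <- as.integer(window)
  if (length(plantedFreqs) > 2L * window) {
    stop("window too small for the number of planted genes", call. = FALSE)
  }
  planted <- .normalizeGeneName(names(plantedFreqs))
  withSeed(.generatorSeed(seed, "operon"), {
    rows <- vector("list", nGenomes)
    focalLoci <- character(nGenomes)
    for (g in seq_len(nGenomes)) {
      genome <- sprintf("genome%03d", g)
      nSlots <- 2L * window + 1L
      focalSlot <- window + 1L
      genes <- rep(NA_character_, nSlots)
      present <- stats::runif(length(plantedFreqs)) < plantedFreqs
      free <- setdiff(seq_len(nSlots), focalSlot)
      if (any(present)) {
        slots <- sample(free, sum(present))
        genes[slots] <- planted[present]
      }
      filler <- which(is.na(genes) & seq_len(nSlots) != focalSlot)
      genes[filler] <- sprintf("fill_%s_%02d", genome, seq_along(filler))
      genes[focalSlot] <- "tatc"
      strands <- sample(c("+", "-"), nSlots, replace = TRUE)
      starts <- seq_len(nSlots) * 1500L - 1400L
      tags <- sprintf("%s_%04d", genome, seq_len(nSlots))
      focalLoci[g] <- tags[focalSlot]
      rows[[g]] <- data.frame(
        genome_id = genome, contig_id = paste0(genome, "_c1"),
        locus_tag = tags, gene_name = genes,
        start = starts, end = starts + 899L, strand = strands,
        product = paste(genes, "product"), stringsAsFactors = FALSE
      )
    }
  })
  structure(list(
    features = do.call(rbind, rows), focalLoci = focalLoci,
    truth = stats::setNames(as.numeric(plantedFreqs), planted),
    window = window, seed = seed
  ), class = "SimulatedOperonSet")
}

#' Write an annotation data.frame in the minimal feature-TSV dialect
#'
#' The written file round-trips through [readFeatures()] with
#' `format = "tsv"`.
#'
#' @param features Annotation `data.frame` (output schema of
#'   [readFeatures()] / [simulateOperonTables()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTsv <- function(features, path) {
  out <- data.frame(
    genome_id = features$genome_id, contig = features$contig_id,
    locus_tag = features$locus_tag, gene = features$gene_name,
    start = features$start, end = features$end, strand = features$strand,
    product = features$product, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a multi-spanning membrane protein with known TM intervals
#'
#' Alternates hydrophilic linkers (residues drawn from R, K, D, E, S, T, N,
#' Q, G, P) with strongly hydrophobic TM segments (residues drawn from I, L,
#' V, F, A, M) of fixed length, emulating a six-TM alpha-helical membrane
#' protein architecture. Optionally derives noisy pseudo-predictions by
#' jittering each true interval's endpoints, to exercise the consensus rule.
#'
#' @param nTm Number of TM segments (default 6).
#' @param tmLength TM segment length in residues (default 21).
#' @param linkerLength Linker length in residues (default 20).
#' @param seed Integer master seed (TM generator stream).
#' @param nPredictors Number of noisy pseudo-predictions to derive
#'   (default 0).
#' @param jitter Maximum absolute endpoint displacement for
#'   pseudo-predictions (default 2).
#' @return A list of class `SimulatedTmProtein` with `protein` (string),
#'   `truth` (a [TMPrediction-class] holding the planted intervals) and
#'   `predictions` (list of jittered `TMPrediction`s, possibly empty).
#' @export
simulateTmProtein <- function(nTm = 6L, tmLength = 21L, linkerLength = 20L,
                              seed = 1L, nPredictors = 0L, jitter = 2L) {
  nTm <- as.integer(nTm)
  if (nTm < 0L) stop("nTm must be >= 0", call. = FALSE)
  philic <- c("R", "K", "D", "E", "S", "T", "N", "Q", "G", "P")
  phobic <- c("I", "L", "V", "F", "A", "M")
  withSeed(.generatorSeed(seed, "tm"), {
    parts <- character(0)
    starts <- integer(0)
    pos <- 0L
    addLinker <- function() {
      parts <<- c(parts, paste(sample(philic, linkerLength, TRUE), collapse = ""))
      pos <<- pos + linkerLength
    }
    addLinker()
    for (k in seq_len(nTm)) {
      starts <- c(starts, pos + 1L)
      parts <- c(parts, paste(sample(phobic, tmLength, TRUE), collapse = ""))
      pos <- pos + tmLength
      addLinker()
    }
    protein <- paste(parts, collapse = "")
    n <- nchar(protein)
    truthIv <- if (nTm > 0L) {
      IRanges::IRanges(start = starts, end = starts + tmLength - 1L)
    } else IRanges::IRanges()
    truth <- TMPrediction("sim_tm", "truth", truthIv, n)
    predictions <- lapply(seq_len(nPredictors), function(p) {
      if (nTm == 0L) {
        return(TMPrediction("sim_tm", sprintf("pseudo%d", p),
                            IRanges::IRanges(), n))
      }
      s <- pmax(1L, IRanges::start(truthIv) +
                  sample.int(2L * jitter + 1L, nTm, TRUE) - jitter - 1L)
      e <- pmin(n, IRanges::end(truthIv) +
                  sample.int(2L * jitter + 1L, nTm, TRUE) - jitter - 1L)
      TMPrediction("sim_tm", sprintf("pseudo%d", p),
                   IRanges::IRanges(start = s, end = pmax(s, e)), n)
    })
  })
  structure(list(protein = protein, truth = truth,
                 predictions = predictions, seed = seed),
            class = "SimulatedTmProtein")
}
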