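# Gene-neighborhood (operon context) analysis: annotation input, extraction
# of +/- N-gene windows around focal loci, per-gene association frequencies
# and conservation classes.

.normalizeGeneName <- function(gene, product = NULL) {
  gene <- tolower(trimws(gene))
  gene <- sub("\\.[0-9]+$", "", gene)  # strip version suffixes
  if (!is.null(product)) {
    noName <- is.na(gene) | !nzchar(gene)
    if (any(noName)) {
      prod <- tolower(trimws(product[noName]))
      prod <- gsub("[^a-z0-9]+", "_", prod)
      prod <- sub("^_+", "", sub("_+$", "", prod))
      gene[noName] <- ifelse(nzchar(prod), prod, NA_character_)
    }
  }
  gene
}

.FEATURE_COLS <- c("genome_id", "contig_id", "locus_tag", "gene_name",
                   "start", "end", "strand", "product")

#' Read a genome annotation table
#'
#' Reads gene features from GFF3 (via `rtracklayer`) or from a minimal TSV
#' dialect with columns `genome_id`, `contig`, `locus_tag`, `gene`, `start`,
#' `end`, `strand`, `product`. Features are sorted by start coordinate
#' within each contig and gene names are normalized (lower-cased, version
#' suffixes stripped; unnamed genes fall back to a token derived from their
#' product string).
#'
#' @param path Annotation file path.
#' @param format `"tsv"` or `"gff3"`.
#' @param genomeId Genome identifier for GFF3 input (which does not carry
#'   one); defaults to the file name without extension.
#' @param featureType GFF3 feature type to keep (default `"gene"`; all
#'   features are kept if none matches).
#' @return `data.frame` with columns `genome_id`, `contig_id`, `locus_tag`,
#'   `gene_name`, `start`, `end`, `strand`, `product`.
#' @export
readFeatures <- function(path, format = c("tsv", "gff3"),
                         genomeId = NULL, featureType = "gene") {
  format <- match.arg(format)
  .assertFileExists(path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("genome_id", "contig", "locus_tag", "gene", "start", "end",
              "strand", "product")
    if (!all(need %in% names(tab))) {
      stop(sprintf("feature TSV must have columns: %s",
                   paste(need, collapse = ", ")), call. = FALSE)
    }
    feats <- data.frame(
      genome_id = as.character(tab$genome_id),
      contig_id = as.character(tab$contig),
      locus_tag = as.character(tab$locus_tag),
      gene_name = .normalizeGeneName(as.character(tab$gene),
                                     as.character(tab$product)),
      start = as.integer(tab$start), end = as.integer(tab$end),
      strand = as.character(tab$strand),
      product = as.character(tab$product),
      stringsAsFactors = FALSE
    )
  } else {
    if (is.null(genomeId)) genomeId <- tools::file_path_sans_ext(basename(path))
    gr <- rtracklayer::import(path, format = "gff3")
    if (!is.null(featureType) && any(gr$type == featureType)) {
      gr <- gr[gr$type == featureType]
    }
    mc <- S4Vectors::mcols(gr)
    getCol <- function(name) {
      if (name %in% names(mc)) as.character(mc[[name]]) else
        rep(NA_character_, length(gr))
    }
    locus <- getCol("locus_tag")
    if (all(is.na(locus))) locus <- getCol("ID")
    feats <- data.frame(
      genome_id = genomeId,
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      locus_tag = locus,
      gene_name = .normalizeGeneName(getCol("gene"), getCol("product")),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      product = getCol("product"),
      stringsAsFactors = FALSE
    )
  }
  bad <- which(is.na(feats$start) | is.na(feats$end) | feats$end < feats$start)
  if (length(bad)) {
    stop(sprintf("feature %d ('%s'): end < start or missing coordinates",
                 bad[1L], feats$locus_tag[bad[1L]]), call. = FALSE)
  }
  if (!all(feats$strand %in% c("+", "-"))) {
    i <- which(!feats$strand %in% c("+", "-"))[1L]
    stop(sprintf("feature '%s': missing or invalid strand '%s'",
                 feats$locus_tag[i], feats$strand[i]), call. = FALSE)
  }
  dup <- feats$locus_tag[duplicated(feats[, c("genome_id", "locus_tag")])]
  if (length(dup)) {
    stop(sprintf("duplicate locus_tag within genome: '%s'", dup[1L]),
         call. = FALSE)
  }
  ord <- order(feats$genome_id, feats$contig_id, feats$start)
  feats <- feats[ord, , drop = FALSE]
  rownames(feats) <- NULL
  feats
}

#' Extract the +/- N gene neighborhood of a focal locus
#'
#' Takes up to `window` genes on each side of the focal gene, in genomic
#' order on the focal contig, truncating at contig ends. Strand relation to
#' the focal gene is recorded per neighbor.
#'
#' @param features Annotation `data.frame` from [readFeatures()].
#' @param focalLocus `locus_tag` of the focal gene.
#' @param window Genes per side (default 10).
#' @param group Optional group label carried on the neighborhood (e.g. a
#'   paralog class such as an isoform clade).
#' @return An object of class `GeneNeighborhood`: a list with `focal` (the
#'   focal feature row), `neighbors` (features plus `relative_position` in
#'   `-window..-1, +1..+window` and `same_strand`), `window` and `group`.
#' @export
extractNeighborhood <- function(features, focalLocus, window = 10L,
                                group = NA_character_) {
  window <- as.integer(window)
  hit <- which(features$locus_tag == focalLocus)
  if (length(hit) == 0L) {
    stop(sprintf("locus '%s' not found in annotation", focalLocus), call. = FALSE)
  }
  hit <- hit[1L]
  focal <- features[hit, , drop = FALSE]
  contig <- features[features$genome_id == focal$genome_id &
                     features$contig_id == focal$contig_id, , drop = FALSE]
  contig <- contig[order(contig$start), , drop = FALSE]
  pos <- which(contig$locus_tag == focalLocus)
  lo <- max(1L, pos - window)
  hi <- min(nrow(contig), pos + window)
  idx <- setdiff(seq.int(lo, hi), pos)
  neighbors <- contig[idx, , drop = FALSE]
  neighbors$relative_position <- idx - pos
  neighbors$same_strand <- neighbors$strand == focal$strand
  neighbors <- neighbors[order(abs(neighbors$relative_position)), , drop = FALSE]
  rownames(neighbors) <- NULL
  structure(
    list(focal = focal, neighbors = neighbors, window = window,
         group = group),
    class = "GeneNeighborhood"
  )
}

#' @export
print.GeneNeighborhood <- function(x, ...) {
  cat(sprintf("GeneNeighborhood around '%s' (%s): %d upstream, %d downstream\n",
              x$focal$locus_tag, x$focal$genome_id,
              sum(x$neighbors$relative_position < 0),
              sum(x$neighbors$relative_position > 0)))
  invisible(x)
}

# presence table of one neighborhood: one row per distinct gene name
.neighborhoodPresence <- function(nb, synonyms) {
  nn <- nb$neighbors
  genes <- nn$gene_name
  if (!is.null(synonyms)) {
    mapped <- synonyms[genes]
    genes <- ifelse(is.na(mapped), genes, mapped)
  }
  keep <- !is.na(genes)
  if (!any(keep)) return(NULL)
  df <- data.frame(gene_name = genes[keep],
                   relative_position = nn$relative_position[keep],
                   same_strand = nn$same_strand[keep],
                   stringsAsFactors = FALSE)
  # collapse duplicates: presence only, nearest copy's position, strand
  # relation 'mixed' when copies disagree
  split <- split(df, df$gene_name)
  do.call(rbind, lapply(split, function(d) {
    nearest <- d[which.min(abs(d$relative_position)), , drop = FALSE]
    rel <- if (all(d$same_strand)) "same"
           else if (!any(d$same_strand)) "opposite" else "mixed"
    data.frame(gene_name = nearest$gene_name,
               relative_position = nearest$relative_position,
               strand_relation = rel, stringsAsFactors = FALSE)
  }))
}

.modal <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1L]
}

#' Gene association frequencies around focal loci
#'
#' Tallies, over a set of focal-locus neighborhoods, how often each gene
#' name occurs (at most once per neighborhood, regardless of copy number)
#' and reports the association frequency `freq = n_gene / O`, where `O` is
#' the number of neighborhoods examined. The number of positions examined
#' per neighborhood (`n_locus = 2 * window`) is reported alongside; the
#' literal product `(n_gene / n_locus) * O` is available as an optional
#' `paper_formula` column. When neighborhoods carry a group label, per-group
#' rows are appended below the overall (`group = "all"`) rows.
#'
#' @param neighborhoods List of `GeneNeighborhood` objects (see
#'   [extractNeighborhood()]).
#' @param synonyms Optional named character vector mapping alternative gene
#'   names to canonical ones (names are matched after normalization).
#' @param paperFormula Add the literal-equation column (default `FALSE`).
#' @return `data.frame` ordered by `freq` (descending) with columns `group`,
#'   `gene_name`, `n_gene`, `O`, `n_locus`, `freq`,
#'   `modal_relative_position`, `modal_strand_relation`.
#' @export
geneAssociationFrequency <- function(neighborhoods, synonyms = NULL,
                                     paperFormula = FALSE) {
  if (length(neighborhoods) < 1L) {
    stop("at least one neighborhood required", call. = FALSE)
  }
  if (!is.null(synonyms)) {
    names(synonyms) <- .normalizeGeneName(names(synonyms))
    synonyms <- .normalizeGeneName(synonyms)
    synonyms <- stats::setNames(as.character(synonyms), names(synonyms))
  }
  groups <- vapply(neighborhoods, function(nb) nb$group, character(1))
  tally <- function(nbs, label) {
    pres <- lapply(nbs, .neighborhoodPresence, synonyms = synonyms)
    pres <- do.call(rbind, pres)
    O <- length(nbs)
    nLocus <- 2L * nbs[[1L]]$window
    if (is.null(pres) || nrow(pres) == 0L) {
      return(data.frame(group = character(), gene_name = character(),
                        n_gene = integer(), O = integer(), n_locus = integer(),
                        freq = numeric(), modal_relative_position = integer(),
                        modal_strand_relation = character(),
                        stringsAsFactors = FALSE))
    }
    split <- split(pres, pres$gene_name)
    out <- do.call(rbind, lapply(split, function(d) {
      data.frame(
        group = label, gene_name = d$gene_name[1L],
        n_gene = nrow(d), O = O, n_locus = nLocus,
        freq = nrow(d) / O,
        modal_relative_position = as.integer(.modal(d$relative_position)),
        modal_strand_relation = .modal(d$strand_relation),
        stringsAsFactors = FALSE
      )
    }))
    out[order(-out$freq, out$gene_name), , drop = FALSE]
  }
  res <- tally(neighborhoods, "all")
  if (any(!is.na(groups))) {
    for (g in sort(unique(groups[!is.na(groups)]))) {
      res <- rbind(res, tally(neighborhoods[which(groups == g)], g))
    }
  }
  if (paperFormula) res$paper_formula <- (res$n_gene / res$n_locus) * res$O
  rownames(res) <- NULL
  res
}

#' Classify gene-association conservation
#'
#' Assigns each gene a conservation class from its association frequency:
#' `"high"` for `freq >= high`, `"moderate"` for `moderate <= freq < high`,
#' `"below"` otherwise (defaults 0.80 and 0.50, the operon-map conventions).
#'
#' @param table Output of [geneAssociationFrequency()].
#' @param moderate,high Class thresholds as fractions (defaults 0.5, 0.8).
#' @return The table with a `conservation_class` column, ordered by `freq`
#'   descending within group.
#' @export
classifyGeneConservation <- function(table, moderate = 0.5, high = 0.8) {
  if (!(moderate >= 0 && moderate < high && high <= 1)) {
    stop("thresholds must satisfy 0 <= moderate < high <= 1", call. = FALSE)
  }
  table$conservation_class <- ifelse(
    table$freq >= high, "high",
    ifelse(table$freq >= moderate, "moderate", "below")
  )
  table[order(table$group, -table$freq, table$gene_name), , drop = FALSE]
}

#' Operon-diagram structure for plotting
#'
#' Builds a JSON-ready list describing, for each relative position in
#' `-window..+window`, the most frequent gene and its conservation class --
#' the information content of a neighborhood-map figure.
#'
#' @param neighborhoods List of `GeneNeighborhood` objects.
#' @param classified Output of [classifyGeneConservation()] over the same
#'   neighborhoods.
#' @return A list (one element per occupied relative position) with
#'   `relative_position`, `gene_name`, `freq`, `conservation_class`.
#' @export
operonDiagram <- function(neighborhoods, classified) {
  window <- neighborhoods[[1L]]$window
  all <- classified[classified$group == "all", , drop = FALSE]
  slots <- lapply(setdiff(seq.int(-window, window), 0L), function(rp) {
    cand <- all[all$modal_relative_position == rp, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    best <- cand[which.max(cand$freq), , drop = FALSE]
    list(relative_position = rp, gene_name = best$gene_name,
         freq = best$freq, conservation_class = best$conservation_class)
  })
  Filter(Negate(is.null), slots)
}
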