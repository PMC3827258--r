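# Transmembrane-topology handling: per-residue TM predictions as interval
# sets, a built-in Kyte-Doolittle hydropathy predictor, and the multi-
# predictor overlap consensus used to call the membrane-spanning regions.

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
kyteDoolittleScale <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' TMPrediction: transmembrane intervals for one sequence and one predictor
#'
#' @slot sequenceId Sequence identifier.
#' @slot predictor Predictor name (e.g. `"hydropathy"`, `"consensus"`).
#' @slot intervals An [IRanges::IRanges] of 1-based inclusive residue
#'   intervals, disjoint and sorted.
#' @slot seqLength Length of the underlying protein sequence.
#' @export
setClass("TMPrediction",
  representation(sequenceId = "character", predictor = "character",
                 intervals = "IRanges", seqLength = "integer")
)

setValidity("TMPrediction", function(object) {
  iv <- object@intervals
  if (length(iv)) {
    if (min(IRanges::start(iv)) < 1L || max(IRanges::end(iv)) > object@seqLength) {
      return("intervals outside [1, seqLength]")
    }
    if (length(IRanges::reduce(iv, min.gapwidth = 0L)) != length(iv)) {
      return("intervals must be disjoint")
    }
    if (is.unsorted(IRanges::start(iv))) return("intervals must be sorted")
  }
  TRUE
})

#' Construct a TMPrediction
#'
#' @param sequenceId Sequence identifier.
#' @param predictor Predictor name.
#' @param intervals An [IRanges::IRanges], or a 2-column matrix/data.frame of
#'   1-based inclusive `start`, `end` positions.
#' @param seqLength Protein length.
#' @return A validated `TMPrediction`.
#' @export
TMPrediction <- function(sequenceId, predictor, intervals, seqLength) {
  if (!methods::is(intervals, "IRanges")) {
    intervals <- as.data.frame(intervals)
    if (nrow(intervals) == 0L) {
      intervals <- IRanges::IRanges()
    } else {
      intervals <- IRanges::IRanges(start = as.integer(intervals[[1]]),
                                    end = as.integer(intervals[[2]]))
    }
  }
  intervals <- intervals[order(IRanges::start(intervals))]
  methods::new("TMPrediction", sequenceId = as.character(sequenceId),
               predictor = as.character(predictor), intervals = intervals,
               seqLength = as.integer(seqLength))
}

setMethod("show", "TMPrediction", function(object) {
  cat(sprintf("TMPrediction '%s' (%s): %d interval(s) over %d residues\n",
              object@sequenceId, object@predictor, length(object@intervals),
              object@seqLength))
  if (length(object@intervals)) {
    cat(paste(sprintf("  [%d, %d]", IRanges::start(object@intervals),
                      IRanges::end(object@intervals)), collapse = "\n"), "\n")
  }
})

#' Intervals of a TMPrediction
#'
#' @param x A `TMPrediction`.
#' @return Its [IRanges::IRanges] of 1-based inclusive intervals.
#' @export
setGeneric("tmIntervals", function(x) standardGeneric("tmIntervals"))

#' @rdname tmIntervals
#' @export
setMethod("tmIntervals", "TMPrediction", function(x) x@intervals)

# logical per-residue mask of a prediction
.tmMask <- function(pred) {
  mask <- rep(FALSE, pred@seqLength)
  iv <- pred@intervals
  for (k in seq_along(iv)) {
    mask[IRanges::start(iv)[k]:IRanges::end(iv)[k]] <- TRUE
  }
  mask
}

#' Sliding-window hydropathy TM prediction
#'
#' Scores a protein with the mean Kyte-Doolittle hydropathy over a sliding
#' window and reports maximal runs of window centers at or above the
#' threshold, extended to the full window extent, as candidate TM intervals.
#' A self-contained single-predictor stand-in so the multi-predictor
#' consensus rule can be exercised without external topology programs.
#'
#' @param protein Amino-acid string (or `AAString`).
#' @param window Odd window length (default 19, a typical TM helix span).
#' @param threshold Mean-hydropathy cutoff (default 1.6).
#' @param sequenceId Identifier stored on the result.
#' @return A [TMPrediction-class] (empty when the window exceeds the
#'   sequence length). Unknown residues score 0 with a warning.
#' @export
hydropathyPredict <- function(protein, window = 19L, threshold = 1.6,
                              sequenceId = "seq") {
  protein <- toupper(as.character(protein))
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("window must be odd", call. = FALSE)
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  if (window > n) {
    return(TMPrediction(sequenceId, "hydropathy", IRanges::IRanges(), n))
  }
  scale <- kyteDoolittleScale()
  scores <- unname(scale[chars])
  if (anyNA(scores)) {
    warning(sprintf("%d unknown residue(s) scored 0", sum(is.na(scores))))
    scores[is.na(scores)] <- 0
  }
  half <- (window - 1L) %/% 2L
  centers <- seq.int(half + 1L, n - half)
  winMeans <- vapply(centers, function(c) {
    mean(scores[(c - half):(c + half)])
  }, numeric(1))
  hot <- winMeans >= threshold
  if (!any(hot)) {
    return(TMPrediction(sequenceId, "hydropathy", IRanges::IRanges(), n))
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- IRanges::IRanges(
    start = pmax(1L, centers[starts[r$values]] - half),
    end = pmin(n, centers[ends[r$values]] + half)
  )
  iv <- IRanges::reduce(iv)
  TMPrediction(sequenceId, "hydropathy", iv, n)
}

#' Consensus transmembrane regions from multiple predictions
#'
#' The default rule keeps exactly the residues called transmembrane by every
#' predictor (strict per-residue intersection), decomposed into maximal
#' intervals; intervals shorter than `minLength` are dropped. A
#' majority-vote mode (more than half of the predictors) is available as an
#' alternative.
#'
#' @param predictions List of [TMPrediction-class] objects for the same
#'   sequence (same id and length), at least 2.
#' @param minLength Minimum consensus interval length in residues
#'   (default 8).
#' @param mode `"intersection"` (all predictors) or `"majority"`.
#' @return A `TMPrediction` with predictor `"consensus"`.
#' @seealso [tmAgreement()] for the per-residue agreement count.
#' @export
consensusTM <- function(predictions, minLength = 8L,
                        mode = c("intersection", "majority")) {
  mode <- match.arg(mode)
  agree <- tmAgreement(predictions)
  k <- length(predictions)
  need <- if (mode == "intersection") k else floor(k / 2) + 1L
  mask <- agree >= need
  iv <- .maskToIntervals(mask)
  iv <- iv[IRanges::width(iv) >= as.integer(minLength)]
  TMPrediction(predictions[[1L]]@sequenceId, "consensus", iv,
               predictions[[1L]]@seqLength)
}

#' Per-residue predictor agreement count
#'
#' @param predictions List of [TMPrediction-class] objects for the same
#'   sequence.
#' @return Integer vector (one entry per residue) counting how many
#'   predictors call each residue transmembrane.
#' @export
tmAgreement <- function(predictions) {
  if (length(predictions) < 2L) {
    stop("at least 2 predictions required", call. = FALSE)
  }
  ids <- vapply(predictions, function(p) p@sequenceId, character(1))
  lens <- vapply(predictions, function(p) p@seqLength, integer(1))
  if (length(unique(ids)) != 1L) {
    stop(sprintf("predictions refer to different sequences: %s",
                 paste(unique(ids), collapse = ", ")), call. = FALSE)
  }
  if (length(unique(lens)) != 1L) {
    stop("predictions disagree on sequence length", call. = FALSE)
  }
  masks <- vapply(predictions, .tmMask, logical(lens[1L]))
  as.integer(rowSums(masks))
}

.maskToIntervals <- function(mask) {
  if (!any(mask)) return(IRanges::IRanges())
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  IRanges::IRanges(start = starts[r$values], end = ends[r$values])
}

#' Read TM predictions from an interval TSV
#'
#' Expected columns: `sequence_id`, `predictor`, `start`, `end` (1-based
#' inclusive). `seqLength` must be supplied per sequence (named vector) since
#' interval files do not carry it.
#'
#' @param path TSV path.
#' @param seqLengths Named integer vector mapping sequence id to protein
#'   length.
#' @return A list of [TMPrediction-class] objects, one per
#'   (sequence, predictor) pair.
#' @export
readTmPredictions <- function(path, seqLengths) {
  .assertFileExists(path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "predictor", "start", "end")
  if (!all(need %in% names(tab))) {
    stop(sprintf("TM TSV must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  keys <- unique(tab[, c("sequence_id", "predictor")])
  lapply(seq_len(nrow(keys)), function(i) {
    id <- keys$sequence_id[i]
    pr <- keys$predictor[i]
    if (!id %in% names(seqLengths)) {
      stop(sprintf("no sequence length supplied for '%s'", id), call. = FALSE)
    }
    sub <- tab[tab$sequence_id == id & tab$predictor == pr, , drop = FALSE]
    TMPrediction(id, pr, sub[, c("start", "end")], seqLengths[[id]])
  })
}

#' Write TM predictions to an interval TSV
#'
#' @param predictions A [TMPrediction-class] or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeTmIntervals <- function(predictions, path) {
  if (methods::is(predictions, "TMPrediction")) predictions <- list(predictions)
  rows <- lapply(predictions, function(p) {
    iv <- tmIntervals(p)
    if (length(iv) == 0L) return(NULL)
    data.frame(sequence_id = p@sequenceId, predictor = p@predictor,
               start = IRanges::start(iv), end = IRanges::end(iv),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(sequence_id = character(), predictor = character(),
                      start = integer(), end = integer())
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
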