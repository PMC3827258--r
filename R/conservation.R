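# Positional consensus / percent-identity profiling of protein alignments
# and comparison of sub-group profiles against an overall profile.

#' ConservationProfile: per-column consensus and percent identity
#'
#' Holds, for one alignment (or a named subset of its rows), the modal
#' non-gap residue and its percent identity at every column. The denominator
#' includes gapped rows, so gaps depress identity; a gap is never reported as
#' the consensus character.
#'
#' @slot alignmentId Identifier of the alignment profiled.
#' @slot groupLabel Label of the row group (e.g. `"all"`, `"TatCd-like"`).
#' @slot columns `data.frame` with `column_index` (1-based),
#'   `consensus_residue` (`NA` for all-gap columns), `percent_identity`
#'   (0-100), `tie` (logical) and `gap_fraction` (0-1).
#' @export
setClass("ConservationProfile",
  representation(alignmentId = "character", groupLabel = "character",
                 columns = "data.frame")
)

setValidity("ConservationProfile", function(object) {
  cols <- object@columns
  need <- c("column_index", "consensus_residue", "percent_identity",
            "tie", "gap_fraction")
  if (!all(need %in% names(cols))) {
    return(sprintf("columns must contain: %s", paste(need, collapse = ", ")))
  }
  pid <- cols$percent_identity
  if (any(!is.na(pid) & (pid < 0 | pid > 100))) {
    return("percent_identity outside [0, 100]")
  }
  TRUE
})

setMethod("show", "ConservationProfile", function(object) {
  cat(sprintf("ConservationProfile '%s' (group '%s'): %d columns\n",
              object@alignmentId, object@groupLabel, nrow(object@columns)))
  pid <- object@columns$percent_identity
  cat(sprintf("  percent identity: median %.1f, range %.1f-%.1f\n",
              stats::median(pid, na.rm = TRUE), min(pid, na.rm = TRUE),
              max(pid, na.rm = TRUE)))
})

#' Per-column table of a ConservationProfile
#'
#' @param x A `ConservationProfile`.
#' @return The per-column `data.frame` (see [ConservationProfile-class]).
#' @export
setGeneric("profileColumns", function(x) standardGeneric("profileColumns"))

#' @rdname profileColumns
#' @export
setMethod("profileColumns", "ConservationProfile", function(x) x@columns)

#' Consensus residue and percent identity of one alignment column
#'
#' The consensus is the modal non-gap residue, with ties broken
#' lexicographically (and flagged). Percent identity divides the modal count
#' by the total number of rows, including gapped ones.
#'
#' @param residues Character vector of single residues (may include `"-"`).
#' @return A list with `consensus_residue` (`NA` if all-gap),
#'   `percent_identity`, `tie` and `gap_fraction`.
#' @examples
#' columnConsensus(c("A", "A", "-", "-"))  # A, 50 percent
#' @export
columnConsensus <- function(residues) {
  if (length(residues) < 1L) stop("empty column", call. = FALSE)
  residues <- toupper(residues)
  n <- length(residues)
  gapFraction <- sum(residues == "-") / n
  nonGap <- residues[residues != "-"]
  if (length(nonGap) == 0L) {
    return(list(consensus_residue = NA_character_, percent_identity = 0,
                tie = FALSE, gap_fraction = gapFraction))
  }
  counts <- table(nonGap)
  top <- max(counts)
  winners <- sort(names(counts)[counts == top])
  list(
    consensus_residue = winners[1L],
    percent_identity = 100 * top / n,
    tie = length(winners) > 1L,
    gap_fraction = gapFraction
  )
}

#' Positional conservation profile of a protein alignment
#'
#' Applies [columnConsensus()] to every column, optionally restricted to a
#' named subset of rows (a sub-group such as one isoform clade).
#'
#' @param aln A named `AAStringSet` (or named character vector) of
#'   equal-length gapped rows.
#' @param rows Optional character vector of row ids (or integer indices)
#'   defining the group; default all rows.
#' @param groupLabel Label stored on the profile (default `"all"`).
#' @param alignmentId Identifier stored on the profile.
#' @return A [ConservationProfile-class].
#' @export
conservationProfile <- function(aln, rows = NULL, groupLabel = "all",
                                alignmentId = "alignment") {
  if (is.character(aln)) aln <- Biostrings::AAStringSet(aln)
  w <- unique(Biostrings::width(aln))
  if (length(w) != 1L) stop("alignment rows differ in length", call. = FALSE)
  ids <- names(aln)
  if (!is.null(rows)) {
    if (length(rows) == 0L) stop("empty row subset", call. = FALSE)
    if (is.numeric(rows)) rows <- ids[as.integer(rows)]
    unknown <- setdiff(rows, ids)
    if (length(unknown)) {
      stop(sprintf("unknown row id(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    aln <- aln[rows]
  }
  mat <- as.matrix(aln)
  cols <- lapply(seq_len(ncol(mat)), function(j) {
    cc <- columnConsensus(mat[, j])
    data.frame(column_index = j,
               consensus_residue = cc$consensus_residue,
               percent_identity = cc$percent_identity,
               tie = cc$tie, gap_fraction = cc$gap_fraction,
               stringsAsFactors = FALSE)
  })
  methods::new("ConservationProfile", alignmentId = alignmentId,
               groupLabel = groupLabel, columns = do.call(rbind, cols))
}

#' Classify columns as highly / poorly conserved
#'
#' Partitions columns into `"high"`, `"low"` and `"intermediate"` classes by
#' percent identity. By default the thresholds are inclusive: `high` means
#' `percent_identity >= high` and `low` means `percent_identity <= low`;
#' strict inequalities are available via `inclusive = FALSE`.
#'
#' @param profile A [ConservationProfile-class].
#' @param high,low Thresholds in percent (defaults 75 and 25).
#' @param inclusive Whether the thresholds are inclusive (default `TRUE`).
#' @return `data.frame` with `column_index`, `percent_identity`, `class`.
#' @export
classifyColumns <- function(profile, high = 75, low = 25, inclusive = TRUE) {
  stopifnot(methods::is(profile, "ConservationProfile"))
  if (!(low >= 0 && low < high && high <= 100)) {
    stop("thresholds must satisfy 0 <= low < high <= 100", call. = FALSE)
  }
  cols <- profileColumns(profile)
  pid <- cols$percent_identity
  cls <- if (inclusive) {
    ifelse(pid >= high, "high", ifelse(pid <= low, "low", "intermediate"))
  } else {
    ifelse(pid > high, "high", ifelse(pid < low, "low", "intermediate"))
  }
  data.frame(column_index = cols$column_index, percent_identity = pid,
             class = cls, stringsAsFactors = FALSE)
}

#' Compare group conservation profiles against an overall profile
#'
#' Lines up one or more group profiles (e.g. isoform sub-alignments) against
#' the overall profile and flags columns where a group's consensus residue
#' differs from the overall consensus, or where the percent identity shifts
#' by at least `differenceMargin` percentage points.
#'
#' @param overall A [ConservationProfile-class] of all rows.
#' @param groups A list of `ConservationProfile` objects spanning the same
#'   columns (a single profile is also accepted).
#' @param differenceMargin Flagging threshold in percentage points
#'   (default 20).
#' @return `data.frame` with one row per column per group: `column_index`,
#'   `group`, `overall_consensus`, `group_consensus`, `overall_identity`,
#'   `group_identity`, `delta_identity`, `residue_change`, `flagged`.
#' @export
compareGroupProfiles <- function(overall, groups, differenceMargin = 20) {
  stopifnot(methods::is(overall, "ConservationProfile"))
  if (methods::is(groups, "ConservationProfile")) groups <- list(groups)
  oc <- profileColumns(overall)
  out <- lapply(groups, function(g) {
    stopifnot(methods::is(g, "ConservationProfile"))
    gc <- profileColumns(g)
    if (nrow(gc) != nrow(oc)) {
      stop(sprintf("group '%s' spans %d columns but overall spans %d",
                   g@groupLabel, nrow(gc), nrow(oc)), call. = FALSE)
    }
    residueChange <- !is.na(oc$consensus_residue) & !is.na(gc$consensus_residue) &
      oc$consensus_residue != gc$consensus_residue
    delta <- gc$percent_identity - oc$percent_identity
    data.frame(
      column_index = oc$column_index,
      group = g@groupLabel,
      overall_consensus = oc$consensus_residue,
      group_consensus = gc$consensus_residue,
      overall_identity = oc$percent_identity,
      group_identity = gc$percent_identity,
      delta_identity = delta,
      residue_change = residueChange,
      flagged = residueChange | abs(delta) >= differenceMargin,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
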