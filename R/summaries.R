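# Group-level distribution summaries of dS/dN ratios and selection-regime
# classification.

#' Tukey boxplot statistics of a value set
#'
#' Quartiles are computed by linear interpolation between order statistics
#' (quantile type 7); fences sit 1.5 interquartile ranges beyond the
#' quartiles; whiskers are the most extreme values within the fences and
#' values beyond them are outliers. Missing values are dropped first.
#'
#' @param values Numeric vector (e.g. per-sequence mean dS/dN of one
#'   bacterial class).
#' @param groupLabel Label carried on the summary.
#' @return A list with `group_label`, `n`, `median`, `q1`, `q3`, `iqr`,
#'   `lower_fence`, `upper_fence`, `whisker_low`, `whisker_high`,
#'   `outliers`. Groups that are empty after missing-value removal are
#'   reported with `n = 0` and `NA` statistics rather than dropped.
#' @examples
#' boxplotStats(c(1, 2, 3, 4, 100))$outliers  # 100
#' @export
boxplotStats <- function(values, groupLabel = "all") {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) {
    return(list(group_label = groupLabel, n = 0L, median = NA_real_,
                q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
                lower_fence = NA_real_, upper_fence = NA_real_,
                whisker_low = NA_real_, whisker_high = NA_real_,
                outliers = numeric()))
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lowerFence <- q[1] - 1.5 * iqr
  upperFence <- q[3] + 1.5 * iqr
  inside <- values[values >= lowerFence & values <= upperFence]
  list(
    group_label = groupLabel, n = n,
    median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
    lower_fence = lowerFence, upper_fence = upperFence,
    whisker_low = min(inside), whisker_high = max(inside),
    outliers = sort(values[values < lowerFence | values > upperFence])
  )
}

#' Boxplot summaries for several groups
#'
#' @param values Numeric vector.
#' @param groups Factor/character vector parallel to `values`.
#' @return `data.frame` with one row per group and all [boxplotStats()]
#'   fields (outliers collapsed to a comma-separated string).
#' @export
groupBoxplotStats <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  out <- lapply(split(values, groups), function(v) v)
  rows <- lapply(names(out), function(g) {
    s <- boxplotStats(out[[g]], g)
    data.frame(group_label = s$group_label, n = s$n, median = s$median,
               q1 = s$q1, q3 = s$q3, iqr = s$iqr,
               lower_fence = s$lower_fence, upper_fence = s$upper_fence,
               whisker_low = s$whisker_low, whisker_high = s$whisker_high,
               outliers = paste(s$outliers, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Selection-regime class of a mean dS/dN value
#'
#' With distances per synonymous/non-synonymous site, `dS/dN > 1` indicates
#' sequence maintenance under purifying-dominated pressure and `dS/dN < 1`
#' diversification; 1 is the neutral cutoff.
#'
#' @param meanRatio Mean dS/dN value(s); `NA` allowed.
#' @param tolerance Half-width of the neutral boundary (default 1e-9).
#' @return Character vector over `{"diversifying", "neutral_boundary",
#'   "maintained", "uncomputable"}`.
#' @examples
#' selectionClass(c(2.62, 0.5, 1, NA))
#' @export
selectionClass <- function(meanRatio, tolerance = 1e-9) {
  vapply(meanRatio, function(r) {
    if (is.na(r)) return("uncomputable")
    if (r < 0) stop("dS/dN ratio must be >= 0", call. = FALSE)
    if (abs(r - 1) <= tolerance) return("neutral_boundary")
    if (r < 1) "diversifying" else "maintained"
  }, character(1))
}
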