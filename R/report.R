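#' Summarize candidates by donor genus
#'
#' Counts candidates per genus and reports each genus's share of the total,
#' to one decimal place (\code{percent}) and to the nearest integer
#' (\code{percent_int}, the headline form). Rows are ordered by descending
#' count, ties broken lexicographically.
#'
#' @param x Either a candidate table (with a \code{genus} column, one row
#'   per candidate) or a precomputed count table with columns
#'   \code{genus, count}.
#' @return Data frame \code{genus, count, percent, percent_int} with
#'   attribute \code{"total"}.
#' @export
summarize_genera <- function(x) {
  if ("count" %in% colnames(x)) {
    counts <- stats::setNames(as.integer(x$count), x$genus)
  } else if ("genus" %in% colnames(x)) {
    counts <- table(x$genus)
    counts <- stats::setNames(as.integer(counts), names(counts))
  } else {
    stop("summarize_genera: need a 'genus' or a 'genus'+'count' table")
  }
  total <- sum(counts)
  if (total == 0 || length(counts) == 0) {
    out <- data.frame(genus = character(), count = integer(),
                      percent = numeric(), percent_int = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "total") <- 0L
    return(out)
  }
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  out <- data.frame(genus = names(counts), count = unname(counts),
                    percent = round(100 * unname(counts) / total, 1),
                    percent_int = as.integer(round(100 * unname(counts) / total)),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}

#' Histogram of candidate lengths in fixed-width bins
#'
#' Half-open bins \code{[lo, lo + bin)} at \code{bin}-bp steps starting at
#' \code{min_len}, covering the longest candidate.
#'
#' @param candidates Candidate table (uses the \code{length} column, or
#'   \code{end - start} when absent).
#' @param bin Bin width in bp. Default 10.
#' @param min_len First bin edge. Default 100.
#' @return Data frame \code{bin_start, bin_end, count}; counts sum to the
#'   number of candidates.
#' @export
length_histogram <- function(candidates, bin = 10L, min_len = 100L) {
  lens <- if ("length" %in% colnames(candidates)) candidates$length
          else candidates$end - candidates$start
  if (length(lens) == 0)
    return(data.frame(bin_start = integer(), bin_end = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  if (any(lens < min_len))
    stop("length_histogram: candidate shorter than min_len = ", min_len)
  edges <- seq.int(min_len, max(lens) + bin, by = bin)
  idx <- findInterval(lens, edges)
  cnt <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(bin_start = edges[-length(edges)],
             bin_end = edges[-1],
             count = cnt, stringsAsFactors = FALSE)
}

#' Barplot of a candidate length histogram
#'
#' @param hist Output of \code{\link{length_histogram}}.
#' @param ... Passed to \code{\link[graphics]{barplot}}.
#' @return The barplot midpoints, invisibly.
#' @export
plot_length_histogram <- function(hist, ...) {
  graphics::barplot(hist$count,
                    names.arg = hist$bin_start,
                    xlab = "candidate length (bp)", ylab = "count",
                    border = NA, ...)
}
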