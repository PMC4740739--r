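#' Validate candidate LGTs with junction-spanning read pairs
#'
#' A genuine insertion (rather than an assembly chimera) is expected to be
#' bridged by sequencing evidence at both prokaryote-eukaryote junctions.
#' For each candidate, three counts are computed from aligned mate
#' placements on the same scaffold:
#' \itemize{
#'   \item \code{left_spanning_reads} / \code{right_spanning_reads}: mates
#'     whose interval covers the candidate start / end with at least
#'     \code{min_overhang} bp on both sides;
#'   \item \code{bridging_pairs}: pairs with one mate wholly inside the
#'     candidate and the other wholly in flanking sequence.
#' }
#' A candidate is \code{supported} when both junctions have at least
#' \code{s} spanning reads, or at least \code{p} bridging pairs exist. A
#' candidate spanning its entire scaffold has no junctions and is reported
#' \code{not_assessable}, never supported.
#'
#' @param candidates Candidate table (\code{\link{length_filter}} output).
#' @param placements Placements data frame
#'   (\code{\link{read_pair_placements}} / \code{\link{simulate_pairs}}).
#' @param scaffold_lengths Named vector of scaffold lengths (or a scaffold
#'   set), used to detect whole-scaffold candidates.
#' @param min_overhang Minimum overhang in bp on each side of a junction
#'   for a spanning read. Default 20.
#' @param s Minimum spanning reads per junction. Default 1.
#' @param p Minimum bridging pairs. Default 1.
#' @return Data frame \code{candidate_id, left_spanning_reads,
#'   right_spanning_reads, bridging_pairs, status, supported} with
#'   \code{status} in supported/unsupported/not_assessable.
#' @export
validate_junctions <- function(candidates, placements, scaffold_lengths,
                               min_overhang = 20L, s = 1L, p = 1L) {
  if (!is.numeric(scaffold_lengths)) {
    ssl <- as_scaffold_set(scaffold_lengths)
    scaffold_lengths <- stats::setNames(Biostrings::width(ssl), names(ssl))
  }
  if (nrow(placements) > 0 &&
      any(placements$m1_start < 0 | placements$m2_start < 0))
    stop("validate_junctions: negative mate coordinates in placements")
  n <- nrow(candidates)
  out <- data.frame(candidate_id = candidates$candidate_id,
                    left_spanning_reads = 0L, right_spanning_reads = 0L,
                    bridging_pairs = 0L, status = "unsupported",
                    supported = FALSE, stringsAsFactors = FALSE)
  if (n == 0) return(out)
  for (i in seq_len(n)) {
    sc <- candidates$scaffold[i]
    a <- candidates$start[i]; b <- candidates$end[i]
    if (!sc %in% names(scaffold_lengths))
      stop("validate_junctions: candidate on unknown scaffold '", sc, "'")
    L <- scaffold_lengths[[sc]]
    if (a <= 0L && b >= L) {
      out$status[i] <- "not_assessable"
      next
    }
    pl <- placements[placements$scaffold == sc, , drop = FALSE]
    if (nrow(pl) == 0) next
    spans <- function(ms, me, j) ms <= j - min_overhang & me >= j + min_overhang
    left <- sum(spans(pl$m1_start, pl$m1_end, a)) +
            sum(spans(pl$m2_start, pl$m2_end, a))
    right <- sum(spans(pl$m1_start, pl$m1_end, b)) +
             sum(spans(pl$m2_start, pl$m2_end, b))
    inside <- function(ms, me) ms >= a & me <= b
    outside <- function(ms, me) me <= a | ms >= b
    bridging <- sum((inside(pl$m1_start, pl$m1_end) &
                       outside(pl$m2_start, pl$m2_end)) |
                    (inside(pl$m2_start, pl$m2_end) &
                       outside(pl$m1_start, pl$m1_end)))
    out$left_spanning_reads[i] <- left
    out$right_spanning_reads[i] <- right
    out$bridging_pairs[i] <- bridging
    sup <- (left >= s && right >= s) || bridging >= p
    out$supported[i] <- sup
    out$status[i] <- if (sup) "supported" else "unsupported"
  }
  out
}
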