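#' Tile scaffolds into fixed-width windows
#'
#' Consecutive half-open tiles \code{[0,W), [W,2W), ...} per scaffold. A
#' final partial tile is emitted when it is at least \code{min_tail} bp
#' (shorter tails cannot seed an alignment and are dropped).
#'
#' @param scaffolds Scaffold set.
#' @param window Tile width W in bp.
#' @param min_tail Minimum length of the final partial tile (defaults to
#'   the seed word size of \code{\link{scoring_params}}).
#' @return Data frame \code{scaffold, start, end}.
#' @export
window_scaffolds <- function(scaffolds, window = 1000L,
                             min_tail = scoring_params()$k) {
  stopifnot(window > 0)
  ss <- as_scaffold_set(scaffolds)
  lens <- Biostrings::width(ss)
  out <- lapply(seq_along(ss), function(i) {
    L <- lens[i]
    starts <- seq.int(0L, max(0L, L - 1L), by = window)
    ends <- pmin(starts + window, L)
    keep <- (ends - starts) >= pmin(min_tail, window)
    data.frame(scaffold = names(ss)[i], start = starts[keep],
               end = ends[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.empty_intervals <- function() {
  data.frame(scaffold = character(), start = integer(), end = integer(),
             taxon = character(), bitscore = numeric(), evalue = numeric(),
             score = integer(), n_windows = integer(),
             stringsAsFactors = FALSE)
}

#' Search windows against the bacterial database
#'
#' Each tile is searched independently (so E-values reflect the tile
#' length); every bacterial hit's query range is lifted from window-local
#' to scaffold coordinates and becomes one bacterial-similar interval
#' carrying its hit statistics.
#'
#' @param scaffolds Scaffold set the windows tile.
#' @param windows Window table from \code{\link{window_scaffolds}}.
#' @param bacterial_index Seed index over the (masked) bacterial database.
#' @param params \code{\link{scoring_params}}.
#' @return Interval data frame \code{scaffold, start, end, taxon, bitscore,
#'   evalue, score, n_windows} in scaffold coordinates.
#' @export
scan_bacterial <- function(scaffolds, windows, bacterial_index,
                           params = scoring_params()) {
  ss <- as_scaffold_set(scaffolds)
  if (nrow(windows) > 0 && !all(windows$scaffold %in% names(ss)))
    stop("window on unknown scaffold: ",
         setdiff(windows$scaffold, names(ss))[1])
  res <- vector("list", nrow(windows))
  seqs <- as.character(ss)
  for (w in seq_len(nrow(windows))) {
    sc <- windows$scaffold[w]
    tile <- substr(seqs[[sc]], windows$start[w] + 1L, windows$end[w])
    hits <- search_homology(tile, bacterial_index, params)
    if (nrow(hits) == 0) next
    res[[w]] <- data.frame(
      scaffold = sc,
      start = windows$start[w] + hits$qstart,
      end = windows$start[w] + hits$qend,
      taxon = hits$taxon, bitscore = hits$bitscore, evalue = hits$evalue,
      score = hits$score, n_windows = 1L, stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) return(.empty_intervals())
  out <- do.call(rbind, res)
  out <- out[order(out$scaffold, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Counter-screen bacterial-similar intervals against animal hits
#'
#' Under the default \code{bacterial_gt_animal} rule an interval is
#' retained unless an overlapping animal hit (E-value at or below the
#' cutoff) has a bit score greater than or equal to the interval's best
#' bacterial bit score; under \code{absent_animal} any overlapping animal
#' hit removes it. Overlap is evaluated against the bacterial-similar
#' subregion, not the whole tile, and an animal hit only counts when it
#' covers at least \code{params$counter_min_overlap} of the interval (an
#' alignment stopping at an insertion junction may graze the interval by a
#' few bases without constituting animal evidence for it). Retained
#' intervals are unchanged.
#'
#' @param intervals Interval table from \code{\link{scan_bacterial}}.
#' @param animal_hits Animal hits in scaffold coordinates (e.g. from
#'   \code{\link{scan_animal}}).
#' @param params \code{\link{scan_params}} (rule and E-value cutoff).
#' @return The retained subset of \code{intervals}.
#' @export
counter_screen <- function(intervals, animal_hits, params = scan_params()) {
  if (nrow(intervals) == 0) return(intervals)
  if (nrow(animal_hits) == 0) return(intervals)
  ah <- animal_hits[animal_hits$evalue <= params$e_cutoff, , drop = FALSE]
  if (nrow(ah) == 0) return(intervals)
  keep <- logical(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    ovw <- pmin(ah$end, intervals$end[i]) - pmax(ah$start, intervals$start[i])
    need <- params$counter_min_overlap *
      (intervals$end[i] - intervals$start[i])
    ov <- ah$scaffold == intervals$scaffold[i] & ovw > 0 & ovw >= need
    keep[i] <- if (!any(ov)) TRUE
    else if (params$counter_rule == "absent_animal") FALSE
    else all(ah$bitscore[ov] < intervals$bitscore[i])
  }
  out <- intervals[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search windows against the animal database, in scaffold coordinates
#'
#' Companion to \code{\link{scan_bacterial}} for the counter-screen: only
#' the given windows (typically those with bacterial hits) are searched.
#'
#' @param scaffolds Scaffold set.
#' @param windows Window table (subset with bacterial evidence).
#' @param animal_index Seed index over the animal database.
#' @param params \code{\link{scoring_params}}.
#' @return Data frame \code{scaffold, start, end, bitscore, evalue}.
#' @export
scan_animal <- function(scaffolds, windows, animal_index,
                        params = scoring_params()) {
  iv <- scan_bacterial(scaffolds, windows, animal_index, params)
  iv[, c("scaffold", "start", "end", "bitscore", "evalue")]
}

#' Join near-adjacent bacterial-similar intervals
#'
#' Two intervals on the same scaffold are merged when the gap between them
#' is strictly less than \code{gap} bp, transitively to a fixpoint. The
#' merged interval inherits the hit statistics of its highest-bit-score
#' part and sums the contributing window counts.
#'
#' @param intervals Interval table (any order).
#' @param gap Join gap g in bp (strict inequality). Default 50.
#' @return Merged interval table, sorted and disjoint per scaffold.
#' @export
join_intervals <- function(intervals, gap = 50L) {
  if (nrow(intervals) == 0) return(intervals)
  iv <- intervals[order(intervals$scaffold, intervals$start, intervals$end), ,
                  drop = FALSE]
  out <- list()
  cur <- iv[1, , drop = FALSE]
  flush <- function(acc, cur) { acc[[length(acc) + 1L]] <- cur; acc }
  for (i in seq_len(nrow(iv))[-1]) {
    row <- iv[i, , drop = FALSE]
    if (row$scaffold == cur$scaffold && (row$start - cur$end) < gap) {
      if (row$bitscore > cur$bitscore) {
        cur$bitscore <- row$bitscore; cur$evalue <- row$evalue
        cur$taxon <- row$taxon; cur$score <- row$score
      }
      cur$end <- max(cur$end, row$end)
      cur$n_windows <- cur$n_windows + row$n_windows
    } else {
      out <- flush(out, cur)
      cur <- row
    }
  }
  out <- flush(out, cur)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Length-filter joined intervals into LGT candidates
#'
#' Intervals of at least \code{min_len} bp (inclusive) become candidates;
#' the candidate genus is the taxon of its best bacterial hit.
#'
#' @param intervals Joined interval table.
#' @param min_len Minimum candidate length L in bp. Default 100.
#' @return Candidate table: \code{candidate_id, scaffold, start, end,
#'   length, genus, bitscore, evalue, n_windows}.
#' @export
length_filter <- function(intervals, min_len = 100L) {
  keep <- (intervals$end - intervals$start) >= min_len
  iv <- intervals[keep, , drop = FALSE]
  out <- data.frame(
    candidate_id = if (nrow(iv)) sprintf("%s:%d-%d", iv$scaffold, iv$start, iv$end)
                   else character(0),
    scaffold = iv$scaffold, start = iv$start, end = iv$end,
    length = iv$end - iv$start, genus = iv$taxon,
    bitscore = iv$bitscore, evalue = iv$evalue, n_windows = iv$n_windows,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the windowed LGT scan end to end
#'
#' Tiles the scaffolds, searches tiles against the bacterial database,
#' counter-screens tiles with bacterial evidence against the animal
#' database, joins near-adjacent surviving intervals and length-filters
#' them into candidates. Scaffolds called \code{bacterial} by
#' \code{\link{classify_scaffolds}} are excluded from candidate emission.
#'
#' @param scaffolds Scaffold set under screen.
#' @param bacterial_index,animal_index Seed indexes over the two databases.
#' @param params \code{\link{scan_params}}.
#' @param scoring \code{\link{scoring_params}}; its \code{e_cutoff} is
#'   forced to \code{params$e_cutoff}.
#' @param calls Optional scaffold call table from
#'   \code{\link{classify_scaffolds}}.
#' @return Candidate table (see \code{\link{length_filter}}).
#' @export
run_scan <- function(scaffolds, bacterial_index, animal_index,
                     params = scan_params(), scoring = scoring_params(),
                     calls = NULL) {
  scoring$e_cutoff <- params$e_cutoff
  ss <- as_scaffold_set(scaffolds)
  if (!is.null(calls)) {
    drop <- calls$scaffold[calls$call == "bacterial"]
    ss <- ss[!(names(ss) %in% drop)]
  }
  if (length(ss) == 0) return(length_filter(.empty_intervals(), params$min_len))
  win <- window_scaffolds(ss, params$window, min_tail = scoring$k)
  bact <- scan_bacterial(ss, win, bacterial_index, scoring)
  if (nrow(bact) > 0) {
    hit_win <- unique(data.frame(
      scaffold = bact$scaffold,
      start = (bact$start %/% params$window) * params$window,
      stringsAsFactors = FALSE))
    pos <- merge(win, hit_win, by = c("scaffold", "start"))
    pos <- pos[order(pos$scaffold, pos$start), , drop = FALSE]
    animal <- scan_animal(ss, pos, animal_index, scoring)
    bact <- counter_screen(bact, animal, params)
  }
  joined <- if (nrow(bact) > 0) join_intervals(bact, params$join_gap) else bact
  length_filter(joined, params$min_len)
}
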