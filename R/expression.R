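#' Classify candidate expression from coverage tracks
#'
#' Computes the mean per-base coverage of every candidate in every
#' condition track and assigns a three-tier class per condition:
#' \code{none} (mean <= t0), \code{trace} (t0 < mean <= t1) or
#' \code{expressed} (mean > t1). Positions absent from a track count as
#' zero coverage. A candidate is flagged \code{differential} when it is
#' expressed in exactly one condition and has class \code{none} in the
#' other(s) -- the condition-specific pattern of a transcribed LGT.
#'
#' @param candidates Candidate table.
#' @param tracks Named list of coverage data frames
#'   (\code{scaffold, start, end, value}; see \code{\link{read_bedgraph}})
#'   or bedGraph file paths, one per condition.
#' @param t0 Upper bound of the \code{none} class (fold coverage).
#'   Default 0.
#' @param t1 Upper bound of the \code{trace} class. Default 1.
#' @return Data frame with \code{candidate_id}, one \code{mean_<cond>} and
#'   one \code{class_<cond>} column per condition, and \code{differential}.
#' @export
classify_expression <- function(candidates, tracks, t0 = 0.0, t1 = 1.0) {
  stopifnot(t0 < t1)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("classify_expression: 'tracks' must be a named list of conditions")
  tracks <- lapply(tracks, function(tr) {
    if (is.character(tr)) tr <- read_bedgraph(tr)
    .check_track(tr)
    tr
  })
  out <- data.frame(candidate_id = candidates$candidate_id,
                    stringsAsFactors = FALSE)
  classes <- matrix("none", nrow(candidates), length(tracks))
  for (ci in seq_along(tracks)) {
    cond <- names(tracks)[ci]
    tr <- tracks[[ci]]
    means <- vapply(seq_len(nrow(candidates)), function(i) {
      a <- candidates$start[i]; b <- candidates$end[i]
      sel <- tr$scaffold == candidates$scaffold[i] & tr$start < b & tr$end > a
      if (!any(sel)) return(0)
      ov <- pmin(tr$end[sel], b) - pmax(tr$start[sel], a)
      sum(ov * tr$value[sel]) / (b - a)
    }, numeric(1))
    cls <- ifelse(means > t1, "expressed", ifelse(means > t0, "trace", "none"))
    out[[paste0("mean_", cond)]] <- means
    out[[paste0("class_", cond)]] <- cls
    classes[, ci] <- cls
  }
  out$differential <- apply(classes, 1, function(z)
    sum(z == "expressed") == 1 && all(z[z != "expressed"] == "none"))
  if (nrow(candidates) == 0) out$differential <- logical(0)
  out
}

# error on overlapping records with conflicting values
.check_track <- function(tr) {
  need <- c("scaffold", "start", "end", "value")
  if (!all(need %in% colnames(tr)))
    stop("coverage track is missing columns: ",
         paste(setdiff(need, colnames(tr)), collapse = ", "))
  if (nrow(tr) < 2) return(invisible(tr))
  o <- order(tr$scaffold, tr$start)
  tr <- tr[o, , drop = FALSE]
  same <- tr$scaffold[-1] == tr$scaffold[-nrow(tr)]
  ovl <- same & tr$start[-1] < tr$end[-nrow(tr)]
  conflict <- ovl & tr$value[-1] != tr$value[-nrow(tr)]
  if (any(conflict))
    stop("coverage track has overlapping records with conflicting values on ",
         tr$scaffold[-1][conflict][1])
  invisible(tr)
}
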