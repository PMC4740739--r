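#' Run the in-memory screen on simulator output
#'
#' Convenience composition used for evaluation runs: masks the bacterial
#' database, builds both indexes, performs the whole-scaffold searches and
#' triage, runs the windowed scan on the non-bacterial scaffolds, and (when
#' present) validates junctions and classifies expression.
#'
#' @param sim Output of \code{\link{simulate_screen_inputs}} (or any list
#'   with \code{genome}, \code{donors}/\code{bacterial_db}, \code{animal_db},
#'   optional \code{pairs} and \code{coverage}).
#' @param scoring \code{\link{scoring_params}}.
#' @param scan \code{\link{scan_params}}.
#' @param mask \code{\link{mask_params}}.
#' @return List: \code{calls}, \code{candidates}, \code{support} (or NULL),
#'   \code{expression} (or NULL).
#' @export
screen_simulation <- function(sim, scoring = scoring_params(),
                              scan = scan_params(), mask = mask_params()) {
  bact_db <- sim$bacterial_db %||% sim$donors
  mk <- mask_scaffolds(bact_db, mask, mode = "soft")
  bi <- build_index(mk$scaffolds, scoring, db_class = "bacterial")
  ai <- build_index(sim$animal_db, scoring, db_class = "animal")
  bh <- search_scaffolds(sim$genome, bi, scoring)
  ah <- search_scaffolds(sim$genome, ai, scoring)
  calls <- classify_scaffolds(sim$genome, bh, ah)
  cand <- run_scan(sim$genome, bi, ai, scan, scoring, calls = calls)
  sup <- if (!is.null(sim$pairs))
    validate_junctions(cand, sim$pairs, sim$genome) else NULL
  expr <- if (!is.null(sim$coverage))
    classify_expression(cand, sim$coverage) else NULL
  list(calls = calls, candidates = cand, support = sup, expression = expr)
}

#' Compare candidates against an implant truth set
#'
#' A truth implant counts as recovered when at least one candidate on its
#' scaffold overlaps it by at least one base; a candidate with no truth
#' overlap is spurious.
#'
#' @param candidates Candidate table.
#' @param truth Implant truth table (\code{scaffold, start, end}).
#' @return List: \code{n_truth}, \code{n_recovered}, \code{sensitivity},
#'   \code{n_spurious}.
#' @export
recovery_stats <- function(candidates, truth) {
  ov_any <- function(a0, a1, sc, tab)
    any(tab$scaffold == sc & tab$start < a1 & a0 < tab$end)
  n_rec <- if (nrow(truth) == 0) 0L else
    sum(vapply(seq_len(nrow(truth)), function(i)
      ov_any(truth$start[i], truth$end[i], truth$scaffold[i], candidates),
      logical(1)))
  n_spur <- if (nrow(candidates) == 0) 0L else
    sum(!vapply(seq_len(nrow(candidates)), function(i)
      ov_any(candidates$start[i], candidates$end[i], candidates$scaffold[i],
             truth), logical(1)))
  list(n_truth = nrow(truth), n_recovered = n_rec,
       sensitivity = if (nrow(truth) == 0) NA_real_ else n_rec / nrow(truth),
       n_spurious = n_spur)
}

#' Contaminant-scaffold detection accuracy
#'
#' @param calls Output of \code{\link{classify_scaffolds}}.
#' @param contaminants Contaminant truth table (\code{scaffold} column).
#' @return List: \code{recall} (contaminants called bacterial) and
#'   \code{precision} (bacterial calls that are contaminants).
#' @export
contaminant_stats <- function(calls, contaminants) {
  called <- calls$scaffold[calls$call == "bacterial"]
  truth <- contaminants$scaffold
  list(recall = if (length(truth) == 0) NA_real_ else
         mean(truth %in% called),
       precision = if (length(called) == 0) NA_real_ else
         mean(called %in% truth))
}
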