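#' Triage scaffolds into bacterial, host, or ambiguous
#'
#' The first, per-scaffold arm of the screen. For each scaffold the best hit
#' per database class is selected by bit score (ties broken by lower
#' E-value, then lexicographic subject id). A scaffold is called
#' \code{bacterial} when its best bacterial bit score exceeds its best
#' animal bit score \emph{and} bacterial hits cover at least \code{min_cov}
#' of its length (the whole-bacterial-scaffold signature of co-assembled
#' endosymbionts/contaminants); \code{host} when it has no bacterial hit or
#' the animal evidence is at least as strong; \code{ambiguous} otherwise
#' (bacterial-best but low coverage: the LGT-bearing host scaffold case,
#' which the windowed scan handles).
#'
#' @param scaffolds Scaffold set under triage.
#' @param bacterial_hits,animal_hits Hit data frames from
#'   \code{\link{search_scaffolds}} (or \code{\link{read_tabular_hits}})
#'   with \code{qseqid} naming scaffolds.
#' @param min_cov Minimum fraction of scaffold length covered by bacterial
#'   hits for a bacterial call. Default 0.5.
#' @param rrna_subjects Optional character vector of database subject ids
#'   annotated as rRNA; scaffolds with any bacterial hit to one of them get
#'   \code{has_rrna_like_hit = TRUE} (reported, never acted on).
#' @return Data frame of per-scaffold calls, one row per scaffold:
#'   \code{scaffold, length, call, best_bact_bit, best_bact_evalue,
#'   best_bact_taxon, best_animal_bit, best_animal_evalue,
#'   n_bacterial_hits, bacterial_covered_fraction, has_rrna_like_hit}.
#' @export
classify_scaffolds <- function(scaffolds, bacterial_hits, animal_hits,
                               min_cov = 0.5, rrna_subjects = character(0)) {
  ss <- as_scaffold_set(scaffolds)
  lens <- stats::setNames(Biostrings::width(ss), names(ss))
  for (h in list(bacterial_hits, animal_hits)) {
    if (nrow(h) > 0 && !all(h$qseqid %in% names(lens)))
      stop("hit on unknown scaffold: ",
           paste(unique(setdiff(h$qseqid, names(lens)))[1:1], collapse = ", "))
  }
  best_of <- function(h) {
    if (nrow(h) == 0) return(NULL)
    h <- h[order(-h$bitscore, h$evalue, h$sseqid), , drop = FALSE]
    h[!duplicated(h$qseqid), , drop = FALSE]
  }
  bb <- best_of(bacterial_hits)
  ba <- best_of(animal_hits)
  out <- data.frame(scaffold = names(lens), length = unname(lens),
                    call = "host",
                    best_bact_bit = 0, best_bact_evalue = NA_real_,
                    best_bact_taxon = NA_character_,
                    best_animal_bit = 0, best_animal_evalue = NA_real_,
                    n_bacterial_hits = 0L,
                    bacterial_covered_fraction = 0,
                    has_rrna_like_hit = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$scaffold
  if (!is.null(bb)) {
    out[bb$qseqid, "best_bact_bit"] <- bb$bitscore
    out[bb$qseqid, "best_bact_evalue"] <- bb$evalue
    out[bb$qseqid, "best_bact_taxon"] <-
      if ("taxon" %in% colnames(bb)) bb$taxon else bb$sseqid
  }
  if (!is.null(ba)) {
    out[ba$qseqid, "best_animal_bit"] <- ba$bitscore
    out[ba$qseqid, "best_animal_evalue"] <- ba$evalue
  }
  if (nrow(bacterial_hits) > 0) {
    tab <- table(bacterial_hits$qseqid)
    out[names(tab), "n_bacterial_hits"] <- as.integer(tab)
    cov <- tapply(seq_len(nrow(bacterial_hits)), bacterial_hits$qseqid,
                  function(i) {
                    ir <- IRanges::reduce(IRanges::IRanges(
                      bacterial_hits$qstart[i] + 1L, bacterial_hits$qend[i]))
                    sum(IRanges::width(ir))
                  })
    out[names(cov), "bacterial_covered_fraction"] <-
      as.numeric(cov) / lens[names(cov)]
    if (length(rrna_subjects) > 0) {
      rr <- unique(bacterial_hits$qseqid[bacterial_hits$sseqid %in% rrna_subjects])
      out[rr, "has_rrna_like_hit"] <- TRUE
    }
  }
  bact <- out$n_bacterial_hits > 0 &
    out$best_bact_bit > out$best_animal_bit &
    out$bacterial_covered_fraction >= min_cov
  ambi <- out$n_bacterial_hits > 0 &
    out$best_bact_bit > out$best_animal_bit &
    out$bacterial_covered_fraction < min_cov
  out$call[ambi] <- "ambiguous"
  out$call[bact] <- "bacterial"
  rownames(out) <- NULL
  out
}

#' Group bacterial-called scaffolds into per-taxon bins
#'
#' Scaffolds called \code{bacterial} are binned by their best-hit taxon,
#' the way co-assembled symbiont genomes split over multiple scaffolds are
#' summarized.
#'
#' @param calls Output of \code{\link{classify_scaffolds}}.
#' @return Data frame \code{taxon, n_scaffolds, total_length}, sorted by
#'   descending scaffold count then taxon.
#' @export
summarize_bacterial_bins <- function(calls) {
  b <- calls[calls$call == "bacterial", , drop = FALSE]
  if (nrow(b) == 0)
    return(data.frame(taxon = character(), n_scaffolds = integer(),
                      total_length = numeric(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(cbind(n_scaffolds = rep(1L, nrow(b)),
                                total_length = b$length),
                          by = list(taxon = b$best_bact_taxon), FUN = sum)
  agg <- agg[order(-agg$n_scaffolds, agg$taxon), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
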