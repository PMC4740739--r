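#' Build a seed index over a sequence database
#'
#' Constructs an exact k-mer position index over the forward strand of every
#' database sequence (reverse-strand matches are found by searching the
#' reverse complement of the query). Seeds never originate inside
#' soft-masked (lowercase) or ambiguous (N) positions; soft-masked positions
#' remain available to alignment extension.
#'
#' @param db Scaffold set to index (\code{DNAStringSet} or named character;
#'   lowercase letters mark soft-masked positions).
#' @param params \code{\link{scoring_params}}; only the word size \code{k}
#'   is used at build time.
#' @param db_class Database class label attached to hits
#'   (\code{"bacterial"}, \code{"animal"}, or any other label).
#' @return An object of class \code{"seed_index"}.
#' @export
build_index <- function(db, params = scoring_params(), db_class = NA_character_) {
  if (length(db) == 0) stop("cannot build a seed index from an empty database")
  # character input is used verbatim: DNAStringSet coercion would uppercase
  # and thereby erase soft masking
  if (is.character(db)) {
    ss <- db
    if (is.null(names(ss))) names(ss) <- sprintf("seq_%03d", seq_along(ss))
    if (anyDuplicated(names(ss))) stop("scaffold names must be unique")
  } else {
    ss <- as_scaffold_set(db)
  }
  seqs <- as.character(ss)
  ptr <- cpp_build_index(names(ss), unname(seqs), params$k)
  structure(list(ptr = ptr, names = names(ss),
                 lengths = nchar(seqs, type = "bytes"),
                 total_len = sum(as.numeric(nchar(seqs))),
                 k = params$k,
                 taxa = scaffold_taxa(ss),
                 db_class = db_class),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("seed_index:", length(x$names), "sequences,",
      format(x$total_len, big.mark = ","), "bp, k =", x$k,
      if (!is.na(x$db_class)) paste0("(", x$db_class, ")") else "", "\n")
  invisible(x)
}

# smallest raw score whose E-value can pass the cutoff
.min_score_for_cutoff <- function(m, n, params) {
  s <- (log(params$kappa * m * n) - log(params$e_cutoff)) / params$lambda
  max(1L, as.integer(ceiling(s - 1e-9)))
}

#' Search a query against a seed index
#'
#' Seed-and-extend local alignment: exact k-mer seeds are grouped by
#' subject and diagonal, extended without gaps under an X-drop rule, and the
#' surviving high-scoring segment pairs are re-aligned by banded affine-gap
#' Smith-Waterman around their diagonal. Overlapping alignments on the same
#' subject and strand keep the highest-scoring representative. E-values use
#' the Karlin-Altschul formula \eqn{E = K m n e^{-\lambda S}} with m the
#' query length and n the total database length; hits with
#' \eqn{E > } \code{e_cutoff} are discarded. Hits are sorted by ascending
#' E-value, then descending bit score.
#'
#' @param query A single nucleotide string, a named character vector, or a
#'   \code{DNAStringSet} (each element searched independently).
#' @param index A \code{\link{build_index}} result.
#' @param params \code{\link{scoring_params}} (word size must match the
#'   index).
#' @return A hit data frame (see \code{\link{read_tabular_hits}} for the
#'   column convention) with additional columns \code{taxon} and
#'   \code{db_class} from the index metadata. Queries shorter than the word
#'   size yield no hits.
#' @export
search_homology <- function(query, index, params = scoring_params()) {
  stopifnot(inherits(index, "seed_index"))
  if (params$k != index$k)
    stop("word size of params (", params$k, ") differs from the index (",
         index$k, ")")
  if (is(query, "DNAStringSet")) query <- as.character(query)
  if (length(query) > 1 || !is.null(names(query))) {
    if (is.null(names(query))) names(query) <- sprintf("query_%03d", seq_along(query))
    res <- lapply(seq_along(query), function(i) {
      h <- search_homology(unname(query[[i]]), index, params)
      h$qseqid <- rep(names(query)[i], nrow(h))
      h
    })
    res <- do.call(rbind, res)
    rownames(res) <- NULL
    return(res[, c(.hit_cols, "taxon", "db_class")])
  }

  m <- nchar(query)
  empty <- cbind(.empty_hits(),
                 data.frame(taxon = character(), db_class = character()))
  if (m < params$k) return(empty)
  n <- index$total_len
  min_score <- .min_score_for_cutoff(m, n, params)
  trigger <- max(params$k * params$match, min_score - 10L)
  raw <- cpp_search(query, index$ptr, params$match, params$mismatch,
                    params$gap_open, params$gap_extend, params$xdrop,
                    trigger, min_score, params$band)
  if (nrow(raw) == 0) return(empty)
  sseqid <- index$names[raw$subject_i]
  evalue <- params$kappa * m * n * exp(-params$lambda * raw$score)
  bitscore <- (params$lambda * raw$score - log(params$kappa)) / log(2)
  keep <- evalue <= params$e_cutoff
  if (!any(keep)) return(empty)
  df <- data.frame(
    qseqid = "query", sseqid = sseqid[keep],
    pident = 100 * raw$nident[keep] / raw$length[keep],
    length = raw$length[keep], mismatch = raw$mismatch[keep],
    gapopen = raw$gapopen[keep],
    qstart = raw$qstart[keep], qend = raw$qend[keep],
    sstart = raw$sstart[keep], send = raw$send[keep],
    evalue = evalue[keep], bitscore = bitscore[keep],
    score = raw$score[keep],
    strand = ifelse(raw$strand[keep] > 0, "+", "-"),
    stringsAsFactors = FALSE)
  df$taxon <- unname(index$taxa[df$sseqid])
  df$db_class <- index$db_class
  ord <- order(df$evalue, -df$bitscore, df$sseqid, df$qstart)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Search every scaffold of a set against an index
#'
#' @param scaffolds Scaffold set; each scaffold is searched as one query.
#' @param index A \code{\link{build_index}} result.
#' @param params \code{\link{scoring_params}}.
#' @return Combined hit data frame with \code{qseqid} set to scaffold ids.
#' @export
search_scaffolds <- function(scaffolds, index, params = scoring_params()) {
  ss <- as_scaffold_set(scaffolds)
  search_homology(stats::setNames(as.character(ss), names(ss)), index, params)
}
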