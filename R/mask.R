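#' DUST low-complexity masking
#'
#' Identifies low-complexity runs with the DUST triplet-composition score.
#' For a stretch of k overlapping triplets with per-triplet counts
#' \eqn{c_t}, the score is \eqn{\sum_t c_t (c_t - 1) / 2 / (k - 1)}; a
#' stretch is masked when it fits inside a window of \code{params$window}
#' bases and its score exceeds \code{params$level / 10}. Equivalently, every
#' window placement and every sub-window are examined and all qualifying
#' sub-windows are reported as the union of maximal masked intervals,
#' merging runs separated by at most \code{params$linker} bases. Non-ACGT
#' characters (N) break triplets and are never masked.
#'
#' @param x A single nucleotide string, or a scaffold set
#'   (\code{DNAStringSet} / named character vector).
#' @param params A \code{\link{mask_params}} object.
#' @return A data frame with columns \code{scaffold, start, end}
#'   (0-based half-open), sorted and disjoint per scaffold.
#' @export
dust_mask <- function(x, params = mask_params()) {
  if (is.character(x)) {
    seqs <- x
    if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%03d", seq_along(seqs))
  } else {
    seqs <- as.character(as_scaffold_set(x))
  }
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (nchar(s) > 0 && grepl("[^ACGTNacgtn]", s))
      stop("dust_mask: sequence '", names(seqs)[i],
           "' contains characters outside {A,C,G,T,N}")
    iv <- cpp_dust_mask(s, params$window, params$level, params$linker)
    if (nrow(iv) > 0)
      out[[i]] <- data.frame(scaffold = names(seqs)[i],
                             start = iv[, 1], end = iv[, 2],
                             stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Apply mask intervals to sequences
#'
#' @param x A single nucleotide string or a scaffold set.
#' @param intervals Mask intervals as returned by \code{\link{dust_mask}}
#'   (the \code{scaffold} column is matched against sequence names; for a
#'   single unnamed string all intervals are applied).
#' @param mode \code{"soft"} lowercases masked positions; \code{"hard"}
#'   replaces them with N. Length is always preserved.
#' @return Hard-masked sequences keep the container type of the input.
#'   Soft-masked sequences are always returned as a named character vector
#'   (with a \code{taxon} attribute when the input carried taxon labels),
#'   because \code{DNAStringSet} does not preserve letter case.
#' @export
apply_mask <- function(x, intervals, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  single <- is.character(x) && length(x) == 1 && is.null(names(x))
  taxa_in <- if (!single) scaffold_taxa(x) else NULL
  had_taxa <- !single && !identical(unname(taxa_in), names(taxa_in))
  if (single) {
    ss <- c(seq_1 = x)
  } else if (is.character(x)) {
    ss <- x
    if (is.null(names(ss))) names(ss) <- sprintf("seq_%03d", seq_along(ss))
  } else {
    ss <- as.character(as_scaffold_set(x))
  }
  for (i in seq_along(ss)) {
    iv <- if (single) intervals else intervals[intervals$scaffold == names(ss)[i], , drop = FALSE]
    if (nrow(iv) == 0) next
    r <- charToRaw(ss[[i]])
    for (j in seq_len(nrow(iv))) {
      a <- iv$start[j] + 1L; b <- iv$end[j]
      if (a < 1L || b > length(r) || a > b)
        stop("apply_mask: interval [", iv$start[j], ",", iv$end[j],
             ") out of bounds for sequence of length ", length(r))
      if (mode == "hard") {
        r[a:b] <- charToRaw("N")
      } else {
        seg <- r[a:b]
        up <- seg >= charToRaw("A") & seg <= charToRaw("Z")
        seg[up] <- as.raw(as.integer(seg[up]) + 32L)
        r[a:b] <- seg
      }
    }
    ss[[i]] <- rawToChar(r)
  }
  if (single) return(unname(ss))
  if (mode == "soft") {
    # DNAStringSet would uppercase the soft mask, so stay in character
    if (had_taxa) attr(ss, "taxon") <- unname(taxa_in)
    return(ss)
  }
  if (is(x, "DNAStringSet")) {
    out <- Biostrings::DNAStringSet(ss)
    S4Vectors::mcols(out) <- S4Vectors::mcols(x)
    out
  } else ss
}

#' Mask a scaffold set, returning both sequences and intervals
#'
#' Convenience wrapper: runs \code{\link{dust_mask}} on every scaffold and
#' applies the mask.
#'
#' @inheritParams dust_mask
#' @inheritParams apply_mask
#' @return List with elements \code{scaffolds} (masked set) and
#'   \code{intervals} (mask table).
#' @export
mask_scaffolds <- function(x, params = mask_params(), mode = "soft") {
  if (!is.character(x)) x <- as_scaffold_set(x)
  iv <- dust_mask(x, params)
  list(scaffolds = apply_mask(x, iv, mode = mode), intervals = iv)
}
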