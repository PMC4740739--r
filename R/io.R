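#' Coerce to a scaffold set
#'
#' A scaffold set is a named \link[Biostrings]{DNAStringSet}; donor/database
#' sets may carry a \code{taxon} metadata column. Character vectors are
#' accepted and converted.
#'
#' @param x A named character vector or a \code{DNAStringSet}.
#' @param taxon Optional character vector of taxon labels, one per sequence.
#' @return A \code{DNAStringSet} with unique names.
#' @export
as_scaffold_set <- function(x, taxon = NULL) {
  if (is(x, "DNAStringSet")) {
    ss <- x
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("seq_%03d", seq_along(x))
    if (is.null(taxon) && !is.null(attr(x, "taxon"))) taxon <- attr(x, "taxon")
    ss <- Biostrings::DNAStringSet(x)
  } else {
    stop("cannot coerce object of class '", class(x)[1], "' to a scaffold set")
  }
  if (anyDuplicated(names(ss))) stop("scaffold names must be unique")
  if (!is.null(taxon)) {
    stopifnot(length(taxon) == length(ss))
    S4Vectors::mcols(ss)$taxon <- taxon
  }
  ss
}

#' Taxon labels of a scaffold set (or its names when unlabelled)
#' @param x A scaffold set.
#' @return Character vector named by scaffold id.
#' @export
scaffold_taxa <- function(x) {
  tx <- if (is.character(x)) {
    if (!is.null(attr(x, "taxon"))) attr(x, "taxon") else names(x)
  } else {
    mc <- S4Vectors::mcols(x)
    if (!is.null(mc) && "taxon" %in% colnames(mc)) mc$taxon else names(x)
  }
  stats::setNames(as.character(tx), names(x))
}

#' Read / write scaffold sets as FASTA
#'
#' Taxon labels round-trip through a \code{taxon=} tag on the FASTA header.
#'
#' @param path File path.
#' @name fasta_io
#' @return \code{read_scaffolds} returns a \code{DNAStringSet};
#'   \code{write_scaffolds} returns \code{path} invisibly.
NULL

#' @rdname fasta_io
#' @export
read_scaffolds <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  tax <- ifelse(grepl("taxon=", hdr), sub("^.*taxon=(\\S+).*$", "\\1", hdr), NA)
  names(ss) <- id
  if (any(!is.na(tax))) S4Vectors::mcols(ss)$taxon <- ifelse(is.na(tax), id, tax)
  ss
}

#' @rdname fasta_io
#' @param x Scaffold set to write.
#' @export
write_scaffolds <- function(x, path) {
  if (is.character(x)) {
    # written verbatim so soft-masked lowercase survives on disk
    if (is.null(names(x))) names(x) <- sprintf("seq_%03d", seq_along(x))
    taxa <- scaffold_taxa(x)
    hdr <- if (identical(unname(taxa), names(x))) names(x) else
      paste0(names(x), " taxon=", unname(taxa))
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(x)) {
      writeLines(paste0(">", hdr[i]), con)
      s <- x[[i]]
      writeLines(substring(s, seq(1, nchar(s), 70L),
                           pmin(seq(1, nchar(s), 70L) + 69L, nchar(s))), con)
    }
    return(invisible(path))
  }
  x <- as_scaffold_set(x)
  mc <- S4Vectors::mcols(x)
  out <- x
  if (!is.null(mc) && "taxon" %in% colnames(mc))
    names(out) <- paste0(names(x), " taxon=", mc$taxon)
  Biostrings::writeXStringSet(out, path, width = 70L)
  invisible(path)
}

# canonical column order of a hit table (internal, 0-based half-open coords)
.hit_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore",
               "score", "strand")

.empty_hits <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             score = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Read homology hits from 12-column tabular format
#'
#' The on-disk dialect is the standard 12-column tabular hit format (query,
#' subject, percent identity, alignment length, mismatches, gap opens, query
#' start, query end, subject start, subject end, E-value, bit score) with
#' 1-based inclusive coordinates; minus-strand hits carry subject start >
#' subject end. On read, coordinates are converted to the internal 0-based
#' half-open convention with an explicit \code{strand} column.
#'
#' @param path File path.
#' @return A hit data frame.
#' @export
read_tabular_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(.empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12))
    stop("malformed hit row at line ", which(nf != 12)[1], ": expected 12 columns, got ",
         nf[nf != 12][1])
  m <- do.call(rbind, parts)
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  for (j in 3:12) if (anyNA(num(j)))
    stop("malformed hit row at line ", which(is.na(num(j)))[1],
         ": non-numeric value in column ", j)
  qs <- as.integer(num(7)); qe <- as.integer(num(8))
  ss <- as.integer(num(9)); se <- as.integer(num(10))
  strand <- ifelse(ss <= se, "+", "-")
  s0 <- pmin(ss, se) - 1L; s1 <- pmax(ss, se)
  df <- data.frame(
    qseqid = m[, 1], sseqid = m[, 2], pident = num(3),
    length = as.integer(num(4)), mismatch = as.integer(num(5)),
    gapopen = as.integer(num(6)),
    qstart = qs - 1L, qend = qe, sstart = s0, send = s1,
    evalue = num(11), bitscore = num(12),
    score = NA_integer_, strand = strand, stringsAsFactors = FALSE)
  df
}

#' Write homology hits in 12-column tabular format
#'
#' Inverse of \code{\link{read_tabular_hits}}: internal 0-based half-open
#' coordinates become 1-based inclusive, and minus-strand hits are written
#' with subject start > subject end.
#'
#' @param hits A hit data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  if (nrow(hits) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  minus <- hits$strand == "-"
  out_ss <- ifelse(minus, hits$send, hits$sstart + 1L)
  out_se <- ifelse(minus, hits$sstart + 1L, hits$send)
  lines <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.2f",
                   hits$qseqid, hits$sseqid, hits$pident, hits$length,
                   hits$mismatch, hits$gapopen,
                   hits$qstart + 1L, hits$qend, out_ss, out_se,
                   formatC(hits$evalue, format = "e", digits = 2),
                   hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write bedGraph coverage tracks
#'
#' Coverage is held internally as a data frame with columns
#' \code{scaffold, start, end, value} (0-based half-open, as in the file
#' format itself). Parsing and serialization go through
#' \link[rtracklayer]{import} / \link[rtracklayer]{export}.
#'
#' @param path File path.
#' @name bedgraph_io
#' @return \code{read_bedgraph} returns a coverage data frame;
#'   \code{write_bedgraph} returns \code{path} invisibly.
NULL

#' @rdname bedgraph_io
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(scaffold = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = as.numeric(gr$score), stringsAsFactors = FALSE)
}

#' @rdname bedgraph_io
#' @param cov Coverage data frame (\code{scaffold, start, end, value}).
#' @export
write_bedgraph <- function(cov, path) {
  if (nrow(cov) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(cov$scaffold,
                               IRanges::IRanges(cov$start + 1L, cov$end),
                               score = cov$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write mate-pair placements
#'
#' Placement tables record aligned mate intervals on scaffolds:
#' \code{pair_id, scaffold, m1_start, m1_end, m2_start, m2_end, orientation}
#' with 0-based half-open coordinates.
#'
#' @param path File path.
#' @name placements_io
#' @return \code{read_pair_placements} returns a placements data frame;
#'   \code{write_pair_placements} returns \code{path} invisibly.
NULL

#' @rdname placements_io
#' @export
read_pair_placements <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("pair_id", "scaffold", "m1_start", "m1_end", "m2_start",
            "m2_end", "orientation")
  if (!all(need %in% colnames(df)))
    stop("placement table is missing columns: ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  df
}

#' @rdname placements_io
#' @param pairs Placements data frame.
#' @export
write_pair_placements <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write LGT candidates as BED6 and GFF3
#'
#' BED6 uses the candidate genus as the name and the best bacterial bit score
#' (capped at 1000) as the score. GFF3 emits \code{lgt_candidate} features.
#'
#' @param candidates Candidate table from the scan.
#' @param path Output path.
#' @name candidate_export
#' @return \code{path}, invisibly.
NULL

#' @rdname candidate_export
#' @export
write_candidates_bed <- function(candidates, path) {
  if (nrow(candidates) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   candidates$scaffold, candidates$start, candidates$end,
                   candidates$genus,
                   pmin(1000L, as.integer(round(candidates$bitscore))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname candidate_export
#' @export
write_candidates_gff3 <- function(candidates, path) {
  hdr <- "##gff-version 3"
  if (nrow(candidates) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  lines <- sprintf(
    "%s\tlgtscreen\tlgt_candidate\t%d\t%d\t%.1f\t.\t.\tID=%s;genus=%s;evalue=%s",
    candidates$scaffold, candidates$start + 1L, candidates$end,
    candidates$bitscore, candidates$candidate_id, candidates$genus,
    formatC(candidates$evalue, format = "e", digits = 2))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# deterministic TSV writer used across pipeline stages
.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             comment.char = "")
}
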