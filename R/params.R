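#' Scoring and statistics parameters for the homology search engine
#'
#' Bundles the match/mismatch/gap scores of the local aligner, the
#' Karlin-Altschul parameters used to convert raw scores into bit scores and
#' E-values, and the seeding/extension controls. The defaults correspond to
#' the classical +1/-2 nucleotide scheme, for which the published ungapped
#' Karlin-Altschul parameters are lambda = 1.28 and K = 0.46. Bit score and
#' E-value are computed as
#' \deqn{S' = (\lambda S - \ln K) / \ln 2, \qquad E = K m n e^{-\lambda S}}
#' with \eqn{S} the raw alignment score, \eqn{m} the query length and \eqn{n}
#' the total database length (summed over sequences).
#'
#' @param match Match reward (positive integer). Default 1.
#' @param mismatch Mismatch penalty (negative integer). Default -2.
#' @param gap_open Gap opening penalty (negative). A gap of length L costs
#'   \code{gap_open + L * gap_extend}. Default -5.
#' @param gap_extend Gap extension penalty per gapped position (negative).
#'   Default -2.
#' @param lambda Karlin-Altschul lambda for the scoring scheme. Default 1.28.
#' @param kappa Karlin-Altschul K. Default 0.46.
#' @param k Seed word size in bp (exact-match k-mer seeding). Default 11.
#' @param xdrop Score drop-off terminating ungapped extension. Default 20.
#' @param e_cutoff Maximum E-value for a reported hit. Default 1e-5, the
#'   cutoff applied to both the bacterial and the animal searches.
#' @param band Half-width in bp of the diagonal band used during gapped
#'   extension (and of the rectangle padding around the ungapped HSP).
#'   Default 64.
#'
#' @return A list of class \code{"scoring_params"}.
#' @export
scoring_params <- function(match = 1L, mismatch = -2L, gap_open = -5L,
                           gap_extend = -2L, lambda = 1.28, kappa = 0.46,
                           k = 11L, xdrop = 20L, e_cutoff = 1e-5,
                           band = 64L) {
  p <- list(match = as.integer(match), mismatch = as.integer(mismatch),
            gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
            lambda = as.numeric(lambda), kappa = as.numeric(kappa),
            k = as.integer(k), xdrop = as.integer(xdrop),
            e_cutoff = as.numeric(e_cutoff), band = as.integer(band))
  if (p$match <= 0) stop("scoring_params: 'match' must be > 0")
  if (p$mismatch >= 0) stop("scoring_params: 'mismatch' must be < 0")
  if (p$k < 4L) stop("scoring_params: seed word size 'k' must be >= 4")
  if (p$e_cutoff <= 0) stop("scoring_params: 'e_cutoff' must be > 0")
  if (p$band < 1L) stop("scoring_params: 'band' must be >= 1")
  structure(p, class = "scoring_params")
}

#' Parameters for DUST low-complexity masking
#'
#' @param window Window length in bp. Default 64.
#' @param level Score threshold; a region is masked when its triplet score
#'   exceeds \code{level / 10} (so the default of 20 masks regions with
#'   normalized triplet score above 2). Default 20.
#' @param linker Maximum gap in bp between adjacent masked runs that are
#'   merged into one interval. Default 1.
#'
#' @return A list of class \code{"mask_params"}.
#' @export
mask_params <- function(window = 64L, level = 20L, linker = 1L) {
  p <- list(window = as.integer(window), level = as.integer(level),
            linker = as.integer(linker))
  if (p$window < 3L) stop("mask_params: 'window' must be >= 3")
  if (p$level <= 0L) stop("mask_params: 'level' must be > 0")
  if (p$linker < 0L) stop("mask_params: 'linker' must be >= 0")
  structure(p, class = "mask_params")
}

#' Parameters for the windowed LGT scan
#'
#' Defaults follow the screen this package implements: scaffolds are broken
#' into 1,000-bp intervals, bacterial-similar regions less than 50 bp apart
#' are joined (strict inequality), and joined regions of at least 100 bp
#' (inclusive) are retained as candidates.
#'
#' @param window Tile width W in bp. Default 1000.
#' @param join_gap Join gap g in bp; two bacterial-similar intervals on the
#'   same scaffold are merged when the gap between them is strictly less than
#'   g. Default 50.
#' @param min_len Minimum candidate length L in bp, inclusive. Default 100.
#' @param e_cutoff Maximum E-value for hits used by the scan (shared with the
#'   search engine). Default 1e-5.
#' @param counter_rule Counter-screen retention rule. With
#'   \code{"bacterial_gt_animal"} (default) an interval is retained unless an
#'   overlapping animal hit has a bit score at least as high as the
#'   interval's best bacterial bit score; with \code{"absent_animal"} any
#'   overlapping animal hit removes the interval.
#' @param counter_min_overlap Minimum fraction of a bacterial-similar
#'   interval that an animal hit must cover before it counts as
#'   overlapping in the counter-screen. A conserved eukaryotic region
#'   miscalled bacterial is rediscovered over essentially its whole extent
#'   by the animal search, whereas an animal alignment ending at an
#'   insertion junction can graze a genuine bacterial interval by a few
#'   bases; the threshold separates the two. Default 0.5.
#'
#' @return A list of class \code{"scan_params"}.
#' @export
scan_params <- function(window = 1000L, join_gap = 50L, min_len = 100L,
                        e_cutoff = 1e-5,
                        counter_rule = c("bacterial_gt_animal", "absent_animal"),
                        counter_min_overlap = 0.5) {
  counter_rule <- match.arg(counter_rule)
  p <- list(window = as.integer(window), join_gap = as.integer(join_gap),
            min_len = as.integer(min_len), e_cutoff = as.numeric(e_cutoff),
            counter_rule = counter_rule,
            counter_min_overlap = as.numeric(counter_min_overlap))
  if (p$counter_min_overlap < 0 || p$counter_min_overlap > 1)
    stop("scan_params: 'counter_min_overlap' must be in [0, 1]")
  if (p$window < p$min_len) stop("scan_params: 'window' must be >= 'min_len'")
  if (p$join_gap < 0L) stop("scan_params: 'join_gap' must be >= 0")
  structure(p, class = "scan_params")
}
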