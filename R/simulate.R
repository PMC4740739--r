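#' Configuration for the truth-tracked genome simulator
#'
#' The simulator emulates the data the screen assumes: random host
#' scaffolds, bacterial donor genomes with a GC offset (so detection is
#' driven by implanted sequence identity rather than composition), implanted
#' LGT segments decayed by i.i.d. substitutions at rate \code{divergence},
#' whole contaminant scaffolds (co-assembled symbiont style), mate pairs
#' sampled over implant junction neighbourhoods, and per-condition
#' expression coverage tracks.
#'
#' @param seed Integer RNG seed; every simulator operation derives its
#'   stream from it (same config, byte-identical outputs).
#' @param n_host_scaffolds Number of host scaffolds. Default 10.
#' @param host_scaffold_length Host scaffold length in bp. Default 100000.
#' @param host_gc Host GC fraction in [0, 1]. Default 0.35, an insect-like
#'   AT-rich composition.
#' @param n_donor_taxa Number of bacterial donor genomes. Default 3.
#' @param donor_length Donor genome length in bp. Default 50000.
#' @param donor_gc_offset Donor GC = host GC + offset, capped at 0.8.
#'   Default 0.10.
#' @param n_implants Number of implanted LGT segments. Default 20.
#' @param implant_length_min,implant_length_max Implant length range in bp,
#'   sampled uniformly. Defaults 150 and 2000.
#' @param divergence Per-site substitution probability d applied to each
#'   implant (post-insertion decay). Default 0.05.
#' @param min_implant_spacing Minimum distance in bp between implants on a
#'   scaffold (and from scaffold ends), so the candidate join rule can never
#'   merge distinct truths. Default 2000.
#' @param n_contaminant_scaffolds Whole donor-derived scaffolds appended to
#'   the assembly. Default 2.
#' @param contaminant_divergence Substitution rate applied to contaminant
#'   scaffolds. Default 0.02.
#' @param pair_insert_mean,pair_insert_sd Mate-pair insert size (bp), mean
#'   and sd. Defaults 500 and 50.
#' @param read_length Read length in bp. Default 100.
#' @param pair_depth Physical (fragment) fold-coverage over each implant
#'   junction. Default 30.
#' @param expressed_fraction Probability that an implant is transcribed in
#'   condition A. Default 0.1.
#' @param expression_depth Uniform fold-coverage given to expressed implants
#'   in condition A. Default 50.
#' @param n_animal_transcripts,animal_transcript_length Size of the
#'   host-derived transcript database used as the animal counter-screen
#'   database. Defaults 100 and 1000.
#'
#' @return A validated list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(seed = 1L,
                              n_host_scaffolds = 10L,
                              host_scaffold_length = 100000L,
                              host_gc = 0.35,
                              n_donor_taxa = 3L,
                              donor_length = 50000L,
                              donor_gc_offset = 0.10,
                              n_implants = 20L,
                              implant_length_min = 150L,
                              implant_length_max = 2000L,
                              divergence = 0.05,
                              min_implant_spacing = 2000L,
                              n_contaminant_scaffolds = 2L,
                              contaminant_divergence = 0.02,
                              pair_insert_mean = 500L,
                              pair_insert_sd = 50L,
                              read_length = 100L,
                              pair_depth = 30,
                              expressed_fraction = 0.1,
                              expression_depth = 50,
                              n_animal_transcripts = 100L,
                              animal_transcript_length = 1000L) {
  cfg <- list(seed = as.integer(seed),
              n_host_scaffolds = as.integer(n_host_scaffolds),
              host_scaffold_length = as.integer(host_scaffold_length),
              host_gc = host_gc,
              n_donor_taxa = as.integer(n_donor_taxa),
              donor_length = as.integer(donor_length),
              donor_gc_offset = donor_gc_offset,
              n_implants = as.integer(n_implants),
              implant_length_min = as.integer(implant_length_min),
              implant_length_max = as.integer(implant_length_max),
              divergence = divergence,
              min_implant_spacing = as.integer(min_implant_spacing),
              n_contaminant_scaffolds = as.integer(n_contaminant_scaffolds),
              contaminant_divergence = contaminant_divergence,
              pair_insert_mean = as.integer(pair_insert_mean),
              pair_insert_sd = as.numeric(pair_insert_sd),
              read_length = as.integer(read_length),
              pair_depth = as.numeric(pair_depth),
              expressed_fraction = expressed_fraction,
              expression_depth = as.numeric(expression_depth),
              n_animal_transcripts = as.integer(n_animal_transcripts),
              animal_transcript_length = as.integer(animal_transcript_length))
  chk <- function(ok, field, msg)
    if (!isTRUE(ok)) stop("simulation_config: invalid '", field, "': ", msg)
  chk(cfg$seed >= 0 && cfg$seed < 2^31 - 100, "seed", "must be in [0, 2^31-100)")
  chk(cfg$n_host_scaffolds >= 1, "n_host_scaffolds", "must be >= 1")
  chk(cfg$host_scaffold_length >= 1, "host_scaffold_length", "must be positive")
  chk(cfg$host_gc >= 0 && cfg$host_gc <= 1, "host_gc", "must be in [0, 1]")
  chk(cfg$n_donor_taxa >= 1, "n_donor_taxa", "must be >= 1")
  chk(cfg$donor_length >= 1, "donor_length", "must be positive")
  chk(cfg$n_implants >= 0, "n_implants", "must be >= 0")
  chk(cfg$implant_length_min >= 1, "implant_length_min", "must be >= 1")
  chk(cfg$implant_length_max >= cfg$implant_length_min, "implant_length_max",
      "must be >= implant_length_min")
  chk(cfg$implant_length_max <= cfg$donor_length, "implant_length_max",
      "must be <= donor_length")
  chk(cfg$divergence >= 0 && cfg$divergence <= 1, "divergence",
      "must be in [0, 1]")
  chk(cfg$n_contaminant_scaffolds >= 0, "n_contaminant_scaffolds", "must be >= 0")
  chk(cfg$n_contaminant_scaffolds <= cfg$n_donor_taxa, "n_contaminant_scaffolds",
      "must be <= n_donor_taxa")
  chk(cfg$contaminant_divergence >= 0 && cfg$contaminant_divergence <= 1,
      "contaminant_divergence", "must be in [0, 1]")
  chk(cfg$read_length >= 1, "read_length", "must be positive")
  chk(cfg$pair_insert_mean > 2 * cfg$read_length, "pair_insert_mean",
      "must exceed twice the read length")
  chk(cfg$pair_depth >= 0, "pair_depth", "must be >= 0")
  chk(cfg$expressed_fraction >= 0 && cfg$expressed_fraction <= 1,
      "expressed_fraction", "must be in [0, 1]")
  structure(cfg, class = "simulation_config")
}

# donor genus labels: familiar symbiont genera first, generic names after
.donor_taxa_pool <- function(n) {
  pool <- c("Arsenophonus", "Wolbachia", "Sodalis", "Hamiltonella",
            "Peptoclostridium")
  if (n > length(pool))
    pool <- c(pool, sprintf("Bacterium%02d", seq_len(n - length(pool))))
  pool[seq_len(n)]
}

.rand_seq <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# i.i.d. substitutions at rate d; returns list(seq, n_sub)
.mutate_seq <- function(seq, d) {
  if (d <= 0) return(list(seq = seq, n_sub = 0L))
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < d)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  list(seq = paste(v, collapse = ""), n_sub = length(hit))
}

#' Simulate host scaffolds
#'
#' @param config A \code{\link{simulation_config}}.
#' @return Scaffold set of i.i.d. random host scaffolds at the configured GC.
#' @export
simulate_host <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed + 1L, {
    seqs <- vapply(seq_len(config$n_host_scaffolds), function(i)
      .rand_seq(config$host_scaffold_length, config$host_gc), character(1))
  })
  names(seqs) <- sprintf("scaffold_%03d", seq_along(seqs))
  as_scaffold_set(seqs)
}

#' Simulate bacterial donor genomes
#'
#' Donors are random sequences at \code{host_gc + donor_gc_offset} (capped
#' at 0.8) carrying distinct genus-style taxon labels, a toy-scale stand-in
#' for a multi-species bacterial database.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return Scaffold set with a \code{taxon} metadata column.
#' @export
simulate_donors <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  gc <- min(config$host_gc + config$donor_gc_offset, 0.8)
  withr::with_seed(config$seed + 2L, {
    seqs <- vapply(seq_len(config$n_donor_taxa), function(i)
      .rand_seq(config$donor_length, gc), character(1))
  })
  taxa <- .donor_taxa_pool(config$n_donor_taxa)
  names(seqs) <- paste0("donor_", taxa)
  as_scaffold_set(seqs, taxon = taxa)
}

#' Implant decayed bacterial segments into host scaffolds
#'
#' Each implant is a uniformly chosen donor substring, mutated by i.i.d.
#' substitutions at rate \code{divergence} (the post-insertion decay model),
#' and inserted at a uniform host position. Insertion points on a scaffold
#' keep at least \code{min_implant_spacing} bp between implants and from the
#' scaffold ends. The returned truth records exact post-insertion
#' coordinates (0-based half-open), the donor taxon and the realized
#' divergence.
#'
#' @param host Host scaffold set (from \code{\link{simulate_host}}).
#' @param donors Donor set (from \code{\link{simulate_donors}}).
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{genome} (host with implants; scaffold lengths
#'   grow by the implanted bases) and \code{implants} (truth table:
#'   \code{scaffold, start, end, taxon, donor, donor_start, donor_end,
#'   divergence}).
#' @export
implant_lgts <- function(host, donors, config) {
  stopifnot(inherits(config, "simulation_config"))
  host <- as_scaffold_set(host)
  donors <- as_scaffold_set(donors)
  taxa <- scaffold_taxa(donors)
  hseq <- as.character(host)
  empty_truth <- data.frame(scaffold = character(), start = integer(),
                            end = integer(), taxon = character(),
                            donor = character(), donor_start = integer(),
                            donor_end = integer(), divergence = numeric(),
                            stringsAsFactors = FALSE)
  if (config$n_implants == 0)
    return(list(genome = host, implants = empty_truth))

  withr::with_seed(config$seed + 3L, {
    sp <- config$min_implant_spacing
    scaf_of <- sort(sample(length(hseq), config$n_implants, replace = TRUE))
    # original-coordinate insertion points, spaced >= sp apart per scaffold
    ins_pos <- integer(config$n_implants)
    for (s in unique(scaf_of)) {
      idx <- which(scaf_of == s)
      L <- nchar(hseq[[s]])
      lo <- sp; hi <- L - sp
      if (hi <= lo)
        stop("implant placement error: scaffold ", names(hseq)[s],
             " too short for spacing ", sp)
      ok <- FALSE
      for (try in 1:1000) {
        pts <- sort(sample(lo:hi, length(idx)))
        if (length(pts) == 1 || min(diff(pts)) >= sp) { ok <- TRUE; break }
      }
      if (!ok)
        stop("implant placement error: cannot place ", length(idx),
             " implants with spacing ", sp, " on scaffold ", names(hseq)[s])
      ins_pos[idx] <- pts
    }
    lens <- config$implant_length_min - 1L +
      sample.int(config$implant_length_max - config$implant_length_min + 1L,
                 config$n_implants, replace = TRUE)
    di <- sample(length(donors), config$n_implants, replace = TRUE)
    dlen <- Biostrings::width(donors)
    dstart <- vapply(seq_len(config$n_implants), function(i)
      sample.int(dlen[di[i]] - lens[i] + 1L, 1L) - 1L, integer(1))
    segs <- lapply(seq_len(config$n_implants), function(i) {
      src <- substr(as.character(donors[[di[i]]]), dstart[i] + 1L,
                    dstart[i] + lens[i])
      .mutate_seq(src, config$divergence)
    })
  })

  truth <- vector("list", config$n_implants)
  for (s in unique(scaf_of)) {
    idx <- which(scaf_of == s)                # ins_pos sorted within scaffold
    seq0 <- hseq[[s]]
    pieces <- character(0)
    prev <- 0L
    shift <- 0L
    for (j in seq_along(idx)) {
      i <- idx[j]
      p <- ins_pos[i]
      pieces <- c(pieces, substr(seq0, prev + 1L, p), segs[[i]]$seq)
      truth[[i]] <- data.frame(
        scaffold = names(hseq)[s],
        start = p + shift, end = p + shift + lens[i],
        taxon = unname(taxa[names(donors)[di[i]]]),
        donor = names(donors)[di[i]],
        donor_start = dstart[i], donor_end = dstart[i] + lens[i],
        divergence = segs[[i]]$n_sub / lens[i],
        stringsAsFactors = FALSE)
      shift <- shift + lens[i]
      prev <- p
    }
    pieces <- c(pieces, substr(seq0, prev + 1L, nchar(seq0)))
    hseq[[s]] <- paste(pieces, collapse = "")
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$scaffold, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = as_scaffold_set(hseq), implants = truth)
}

#' Append whole contaminant scaffolds
#'
#' Emulates co-assembled endosymbiont/contaminant genomes: whole donor
#' sequences, lightly mutated, appended as extra scaffolds.
#'
#' @param genome Scaffold set (typically the implanted host genome).
#' @param donors Donor set.
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{genome} (input plus appended scaffolds) and
#'   \code{contaminants} (truth table: \code{scaffold, taxon}).
#' @export
add_contaminants <- function(genome, donors, config) {
  stopifnot(inherits(config, "simulation_config"))
  genome <- as_scaffold_set(genome)
  donors <- as_scaffold_set(donors)
  nc <- config$n_contaminant_scaffolds
  if (nc == 0)
    return(list(genome = genome,
                contaminants = data.frame(scaffold = character(),
                                          taxon = character(),
                                          stringsAsFactors = FALSE)))
  taxa <- scaffold_taxa(donors)
  withr::with_seed(config$seed + 4L, {
    pick <- sample(length(donors), nc)
    seqs <- vapply(pick, function(i)
      .mutate_seq(as.character(donors[[i]]), config$contaminant_divergence)$seq,
      character(1))
  })
  names(seqs) <- sprintf("contam_%s", taxa[names(donors)[pick]])
  out <- c(as.character(genome), seqs)
  list(genome = as_scaffold_set(out),
       contaminants = data.frame(scaffold = names(seqs),
                                 taxon = unname(taxa[names(donors)[pick]]),
                                 stringsAsFactors = FALSE))
}

#' Simulate mate-pair placements over implant junction neighbourhoods
#'
#' For each implant junction, fragment start points are drawn as a Poisson
#' process at rate \code{pair_depth / pair_insert_mean} over the window of
#' fragment placements spanning the junction, so \code{pair_depth} is the
#' expected physical (fragment) coverage of each junction. Each fragment
#' yields two mate intervals of \code{read_length} bp at its ends
#' (forward-reverse orientation); fragments extending past a scaffold end
#' are dropped.
#'
#' @param genome Scaffold set the placements refer to.
#' @param truth Implant truth table from \code{\link{implant_lgts}}.
#' @param config A \code{\link{simulation_config}}.
#' @return Placements data frame: \code{pair_id, scaffold, m1_start, m1_end,
#'   m2_start, m2_end, orientation} (0-based half-open).
#' @export
simulate_pairs <- function(genome, truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  genome <- as_scaffold_set(genome)
  slen <- stats::setNames(Biostrings::width(genome), names(genome))
  ins <- config$pair_insert_mean
  r <- config$read_length
  empty <- data.frame(pair_id = character(), scaffold = character(),
                      m1_start = integer(), m1_end = integer(),
                      m2_start = integer(), m2_end = integer(),
                      orientation = character(), stringsAsFactors = FALSE)
  if (config$pair_depth <= 0 || nrow(truth) == 0) return(empty)
  if (any(slen[unique(truth$scaffold)] < ins))
    stop("insert size ", ins, " exceeds the length of a scaffold carrying implants")
  junctions <- rbind(
    data.frame(scaffold = truth$scaffold, pos = truth$start),
    data.frame(scaffold = truth$scaffold, pos = truth$end))
  rows <- list()
  withr::with_seed(config$seed + 5L, {
    rate <- config$pair_depth / ins
    for (j in seq_len(nrow(junctions))) {
      sc <- junctions$scaffold[j]; pos <- junctions$pos[j]
      lo <- pos - ins + 1L; hi <- pos - 1L         # fragment starts spanning pos
      nfrag <- rpois(1L, rate * (hi - lo + 1L))
      if (nfrag == 0) next
      f <- sample(lo:hi, nfrag, replace = TRUE)
      ilen <- pmax(2L * r + 2L, as.integer(round(rnorm(nfrag, ins,
                                                       config$pair_insert_sd))))
      keep <- f >= 0L & (f + ilen) <= slen[[sc]]
      f <- f[keep]; ilen <- ilen[keep]
      if (length(f) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = sc,
        m1_start = f, m1_end = f + r,
        m2_start = f + ilen - r, m2_end = f + ilen,
        orientation = "FR", stringsAsFactors = FALSE)
    }
  })
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- cbind(pair_id = sprintf("pair_%06d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate per-condition expression coverage over implants
#'
#' Each implant is expressed with probability \code{expressed_fraction};
#' expressed implants receive uniform \code{expression_depth} coverage in
#' condition A and zero in condition B (the male-specific pattern), all
#' other positions zero in both conditions.
#'
#' @param genome Scaffold set (unused beyond the namespace; kept for
#'   interface symmetry).
#' @param truth Implant truth table.
#' @param config A \code{\link{simulation_config}}.
#' @return List of two coverage data frames, \code{condA} and \code{condB},
#'   plus attribute \code{"expressed"} (logical per truth row).
#' @export
simulate_expression <- function(genome, truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  empty <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), value = numeric(),
                      stringsAsFactors = FALSE)
  withr::with_seed(config$seed + 6L, {
    expressed <- if (nrow(truth) == 0) logical(0)
                 else runif(nrow(truth)) < config$expressed_fraction
  })
  condA <- if (any(expressed)) {
    data.frame(scaffold = truth$scaffold[expressed],
               start = truth$start[expressed], end = truth$end[expressed],
               value = config$expression_depth, stringsAsFactors = FALSE)
  } else empty
  out <- list(condA = condA, condB = empty)
  attr(out, "expressed") <- expressed
  out
}

#' Simulate an animal (host-derived) transcript database
#'
#' Random substrings of the pre-implant host scaffolds stand in for the
#' animal transcript database used by the counter-screen.
#'
#' @param host Pre-implant host scaffold set.
#' @param config A \code{\link{simulation_config}}.
#' @return Scaffold set of transcripts labelled \code{db_class}-ready.
#' @export
simulate_animal_db <- function(host, config) {
  stopifnot(inherits(config, "simulation_config"))
  host <- as_scaffold_set(host)
  tl <- min(config$animal_transcript_length,
            min(Biostrings::width(host)))
  withr::with_seed(config$seed + 7L, {
    sc <- sample(length(host), config$n_animal_transcripts, replace = TRUE)
    st <- vapply(sc, function(s)
      sample.int(Biostrings::width(host)[s] - tl + 1L, 1L) - 1L, integer(1))
    seqs <- vapply(seq_along(sc), function(i)
      substr(as.character(host[[sc[i]]]), st[i] + 1L, st[i] + tl),
      character(1))
  })
  names(seqs) <- sprintf("transcript_%03d", seq_along(seqs))
  as_scaffold_set(seqs, taxon = rep("HostAnimal", length(seqs)))
}

#' Generate the full set of screen inputs with ground truth
#'
#' Composes \code{\link{simulate_host}}, \code{\link{simulate_donors}},
#' \code{\link{implant_lgts}}, \code{\link{add_contaminants}},
#' \code{\link{simulate_pairs}}, \code{\link{simulate_expression}} and
#' \code{\link{simulate_animal_db}}. Deterministic given the config.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List: \code{genome}, \code{donors}, \code{animal_db},
#'   \code{truth} (list with \code{implants} and \code{contaminants}),
#'   \code{pairs}, \code{coverage}, \code{host} (pre-implant scaffolds).
#' @export
simulate_screen_inputs <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  host <- simulate_host(config)
  donors <- simulate_donors(config)
  imp <- implant_lgts(host, donors, config)
  con <- add_contaminants(imp$genome, donors, config)
  pairs <- simulate_pairs(con$genome, imp$implants, config)
  coverage <- simulate_expression(con$genome, imp$implants, config)
  animal <- simulate_animal_db(host, config)
  list(genome = con$genome, donors = donors, animal_db = animal,
       truth = list(implants = imp$implants, contaminants = con$contaminants),
       pairs = pairs, coverage = coverage, host = host)
}
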