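# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain dynamic programming and literal
# enumeration.

rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

mutate_dna <- function(x, d) {
  v <- strsplit(x, "")[[1]]
  hit <- which(runif(length(v)) < d)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# full Smith-Waterman with affine gaps (Gotoh), score only;
# a gap of length L costs go + L * ge
oracle_sw_score <- function(q, s, match = 1, mismatch = -2, go = -5, ge = -2) {
  qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
  nq <- length(qv); ns <- length(sv)
  H <- matrix(0, nq + 1, ns + 1)
  E <- matrix(-Inf, nq + 1, ns + 1)
  F <- matrix(-Inf, nq + 1, ns + 1)
  best <- 0
  for (i in 2:(nq + 1)) {
    for (j in 2:(ns + 1)) {
      E[i, j] <- max(H[i - 1, j] + go + ge, E[i - 1, j] + ge)
      F[i, j] <- max(H[i, j - 1] + go + ge, F[i, j - 1] + ge)
      sub <- if (qv[i - 1] == sv[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# literal DUST enumerator: every window placement, every sub-window.
# Returns a two-column matrix of merged 0-based half-open intervals.
oracle_dust <- function(seq, window = 64, level = 20, linker = 1) {
  n <- nchar(seq)
  ch <- strsplit(toupper(seq), "")[[1]]
  is_acgt <- ch %in% c("A", "C", "G", "T")
  masked <- rep(FALSE, n)
  # chunks of consecutive ACGT (N breaks triplets)
  r <- rle(is_acgt)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (ci in which(r$values & r$lengths >= 4)) {
    c0 <- starts[ci]; c1 <- ends[ci]
    L <- c1 - c0 + 1
    trip <- 16 * (match(ch[c0:(c1 - 2)], c("A", "C", "G", "T")) - 1) +
      4 * (match(ch[(c0 + 1):(c1 - 1)], c("A", "C", "G", "T")) - 1) +
      match(ch[(c0 + 2):c1], c("A", "C", "G", "T"))
    ntrip <- L - 2
    wlen <- min(window, L)
    wtrip <- wlen - 2                       # triplets per window placement
    for (w0 in 1:max(1, L - wlen + 1)) {    # window start (1-based in chunk)
      for (i in w0:(w0 + wtrip - 1)) {      # sub-window start triplet
        if (i > ntrip) break
        cnt <- integer(64)
        num <- 0
        jmax <- min(w0 + wtrip - 1, ntrip)
        for (j in i:jmax) {
          t <- trip[j]
          num <- num + cnt[t]
          cnt[t] <- cnt[t] + 1
          k <- j - i + 1
          if (k >= 2 && num / (k - 1) > level / 10) {
            a <- c0 + i - 1; b <- c0 + j + 1   # bases i..j+2 of chunk
            masked[a:b] <- TRUE
          }
        }
      }
    }
  }
  if (!any(masked)) return(matrix(integer(0), 0, 2))
  # merge maximal runs, then bridge gaps <= linker
  rr <- rle(masked)
  e <- cumsum(rr$lengths); s <- e - rr$lengths + 1
  iv <- cbind(s[rr$values] - 1L, e[rr$values])   # 0-based half-open
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] - merged[nrow(merged), 2] <= linker)
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[i, 2])
    else merged <- rbind(merged, iv[i, , drop = FALSE])
  }
  merged
}

# package dust_mask result for one sequence as a plain matrix
dust_as_matrix <- function(df) {
  if (nrow(df) == 0) return(matrix(integer(0), 0, 2))
  unname(cbind(df$start, df$end))
}

# small simulated dataset shared by several tests
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_host_scaffolds = 3, host_scaffold_length = 30000,
         n_implants = 5, n_contaminant_scaffolds = 1, donor_length = 20000,
         n_animal_transcripts = 30),
    list(...))
  do.call(simulation_config, args)
}
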