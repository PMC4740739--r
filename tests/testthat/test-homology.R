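test_that("an exact substring is found with full identity and exact coords", {
  set.seed(1)
  db <- c(subj = rand_dna(2000))
  q <- substr(db, 501, 700)
  sp <- scoring_params()
  h <- search_homology(q, build_index(db, sp), sp)
  expect_equal(nrow(h), 1L)
  expect_equal(h$sseqid, "subj")
  expect_equal(h$pident, 100)
  expect_equal(h$strand, "+")
  expect_equal(c(h$qstart, h$qend), c(0L, 200L))
  expect_equal(c(h$sstart, h$send), c(500L, 700L))
  expect_equal(h$bitscore,
               (sp$lambda * 200 * sp$match - log(sp$kappa)) / log(2),
               tolerance = 1e-12)
  expect_equal(h$evalue, sp$kappa * 200 * 2000 * exp(-sp$lambda * 200),
               tolerance = 1e-12)
})

test_that("reverse-complement queries hit the same locus on the minus strand", {
  set.seed(2)
  db <- c(subj = rand_dna(3000))
  q <- substr(db, 1001, 1400)
  qrc <- revcomp_dna(q)
  sp <- scoring_params()
  idx <- build_index(db, sp)
  hf <- search_homology(q, idx, sp)
  hr <- search_homology(qrc, idx, sp)
  expect_equal(hr$strand[1], "-")
  expect_equal(c(hr$sstart[1], hr$send[1]), c(hf$sstart[1], hf$send[1]))
  expect_equal(hr$score[1], hf$score[1])
  expect_equal(hr$pident[1], hf$pident[1])
})

test_that("every reported raw score equals full Smith-Waterman (oracle)", {
  sp <- scoring_params(k = 5, e_cutoff = 10)
  set.seed(3)
  n_checked <- 0
  for (i in 1:500) {
    slen <- sample(20:60, 1)
    s <- rand_dna(slen)
    qlen <- sample(15:min(60, slen), 1)
    at <- sample(slen - qlen + 1, 1)
    q <- mutate_dna(substr(s, at, at + qlen - 1), runif(1, 0, 0.15))
    idx <- build_index(c(subj = s), sp)
    h <- search_homology(q, idx, sp)
    if (nrow(h) == 0) next
    best <- max(oracle_sw_score(q, s, sp$match, sp$mismatch,
                                sp$gap_open, sp$gap_extend),
                oracle_sw_score(revcomp_dna(q), s, sp$match, sp$mismatch,
                                sp$gap_open, sp$gap_extend))
    expect_equal(max(h$score), best, info = paste("pair", i))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 400)   # the vast majority of pairs produce a hit
})

test_that("identity, mismatch and gap counts are mutually consistent", {
  set.seed(4)
  sp <- scoring_params()
  for (i in 1:25) {
    db <- c(subj = rand_dna(2000))
    q <- mutate_dna(substr(db, 301, 800), 0.05)
    h <- search_homology(q, build_index(db, sp), sp)
    expect_gt(nrow(h), 0)
    # in an ungapped alignment identities + mismatches = alignment length
    ug <- h$gapopen == 0
    expect_equal(h$pident[ug], 100 * (h$length[ug] - h$mismatch[ug]) / h$length[ug],
                 tolerance = 1e-9)
    # substitution-only decay: expect no gaps and ~5% mismatch at the top hit
    expect_equal(h$gapopen[1], 0L)
    expect_gte(h$pident[1], 90)
  }
})

test_that("E-values follow Karlin-Altschul and the cutoff is enforced", {
  set.seed(5)
  db <- c(a = rand_dna(5000), b = rand_dna(3000))
  q <- mutate_dna(substr(db[["a"]], 2001, 2300), 0.08)
  sp <- scoring_params()
  h <- search_homology(q, build_index(db, sp), sp)
  expect_gt(nrow(h), 0)
  m <- nchar(q); n <- 8000
  expect_equal(h$evalue, sp$kappa * m * n * exp(-sp$lambda * h$score),
               tolerance = 1e-12)
  expect_equal(h$bitscore, (sp$lambda * h$score - log(sp$kappa)) / log(2),
               tolerance = 1e-12)
  expect_true(all(h$evalue <= sp$e_cutoff))
  expect_false(is.unsorted(h$evalue))

  # tightening the cutoff keeps a subset of the hits
  sp9 <- scoring_params(e_cutoff = 1e-9)
  h9 <- search_homology(q, build_index(db, sp9), sp9)
  key <- function(x) paste(x$sseqid, x$qstart, x$sstart, x$score)
  expect_true(all(key(h9) %in% key(h)))
  expect_true(all(h9$evalue <= 1e-9))
})

test_that("multi-query input is labelled and equals per-query searches", {
  set.seed(6)
  db <- c(subj = rand_dna(4000))
  qs <- c(q1 = mutate_dna(substr(db, 101, 400), 0.05),
          q2 = rand_dna(300),
          q3 = mutate_dna(substr(db, 2001, 2500), 0.05))
  sp <- scoring_params()
  idx <- build_index(db, sp)
  hall <- search_homology(qs, idx, sp)
  expect_true(all(hall$qseqid %in% c("q1", "q3")))
  for (qn in c("q1", "q2", "q3")) {
    hone <- search_homology(qs[[qn]], idx, sp)
    expect_equal(nrow(hall[hall$qseqid == qn, ]), nrow(hone), info = qn)
  }
})

test_that("word size changes sensitivity in the expected direction", {
  set.seed(7)
  db <- c(subj = rand_dna(3000))
  hits_at_k <- function(k, d) {
    sp <- scoring_params(k = k)
    q <- withr::with_seed(99, mutate_dna(substr(db, 1001, 1150), d))
    nrow(search_homology(q, build_index(db, sp), sp))
  }
  # at high divergence a long word finds nothing where a short word succeeds
  expect_gte(hits_at_k(7, 0.20), hits_at_k(21, 0.20))
  expect_gt(hits_at_k(7, 0.20), 0)
})

test_that("hit tables round-trip through the 12-column tabular format", {
  set.seed(8)
  db <- c(s1 = rand_dna(3000), s2 = rand_dna(2000))
  qs <- c(qa = mutate_dna(substr(db[["s1"]], 501, 900), 0.05),
          qb = revcomp_dna(mutate_dna(substr(db[["s2"]], 101, 600), 0.05)))
  sp <- scoring_params()
  h <- search_homology(qs, build_index(db, sp), sp)
  expect_true(any(h$strand == "-"))
  f <- tempfile(fileext = ".tsv")
  write_tabular_hits(h, f)
  back <- read_tabular_hits(f)
  common <- c("qseqid", "sseqid", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "strand")
  expect_equal(back[common], h[common], ignore_attr = TRUE)
  expect_equal(back$pident, h$pident, tolerance = 1e-6)
  # bitscore is serialized with two decimals
  expect_equal(back$bitscore, h$bitscore, tolerance = 1e-4)
  # on-disk rows are 1-based inclusive with sstart > send on the minus strand
  raw <- read.table(f, sep = "\t", stringsAsFactors = FALSE)
  minus <- which(h$strand == "-")
  expect_true(all(raw$V9[minus] > raw$V10[minus]))
  expect_equal(raw$V7, h$qstart + 1L)
  expect_equal(raw$V8, h$qend)
})

test_that("tabular parse errors carry line numbers", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("q\ts\t100.0\t50\t0\t0\t1\t50\t1\t50\t1e-10\t90.1",
               "q\ts\tnot_a_number\t50\t0\t0\t1\t50\t1\t50\t1e-10\t90.1"), f)
  expect_error(read_tabular_hits(f), "line 2")
  writeLines(c("q\ts\t100.0\t50"), f)
  expect_error(read_tabular_hits(f), "line 1")
})

test_that("queries shorter than the word size and empty inputs are handled", {
  set.seed(9)
  db <- c(subj = rand_dna(500))
  sp <- scoring_params()
  idx <- build_index(db, sp)
  h <- search_homology("ACGTACGT", idx, sp)   # shorter than k = 11
  expect_equal(nrow(h), 0L)
  expect_error(build_index(character(0), sp), "empty")
})

test_that("overlap dedup keeps one alignment per locus", {
  set.seed(10)
  db <- c(subj = rand_dna(4000))
  q <- mutate_dna(substr(db, 1001, 2000), 0.03)
  sp <- scoring_params()
  h <- search_homology(q, build_index(db, sp), sp)
  if (nrow(h) > 1) {
    # no two hits on the same subject and strand overlap in both coordinates
    for (i in seq_len(nrow(h) - 1)) for (j in (i + 1):nrow(h)) {
      if (h$sseqid[i] == h$sseqid[j] && h$strand[i] == h$strand[j]) {
        qo <- h$qstart[i] < h$qend[j] && h$qstart[j] < h$qend[i]
        so <- h$sstart[i] < h$send[j] && h$sstart[j] < h$send[i]
        expect_false(qo && so)
      }
    }
  }
  expect_gte(nrow(h), 1)
})
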