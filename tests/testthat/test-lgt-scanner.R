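mk_iv <- function(scaffold, start, end, taxon = "X", bitscore = 100,
                  evalue = 1e-20, score = 60, n_windows = 1L) {
  data.frame(scaffold = scaffold, start = start, end = end, taxon = taxon,
             bitscore = bitscore, evalue = evalue, score = score,
             n_windows = n_windows, stringsAsFactors = FALSE)
}

test_that("windowing tiles scaffolds in half-open 1,000-bp steps", {
  w <- window_scaffolds(c(a = strrep("A", 2500), b = strrep("C", 1000)))
  expect_equal(w$scaffold, c("a", "a", "a", "b"))
  expect_equal(w$start, c(0L, 1000L, 2000L, 0L))
  expect_equal(w$end, c(1000L, 2000L, 2500L, 1000L))

  # a tail shorter than the word size is dropped
  w2 <- window_scaffolds(c(a = strrep("A", 1005)), min_tail = 11)
  expect_equal(nrow(w2), 1L)
  w3 <- window_scaffolds(c(a = strrep("A", 1011)), min_tail = 11)
  expect_equal(nrow(w3), 2L)
  expect_equal(w3$end[2], 1011L)
})

test_that("window hits lift back to exact scaffold coordinates", {
  # deliberately unalignable flanks around an exact donor fragment placed
  # entirely inside the third tile
  set.seed(30)
  donor <- c(donor_X = rand_dna(5000))
  frag <- substr(donor, 1001, 1400)
  scaf <- c(sc = paste0(rand_dna(2200), frag, rand_dna(1400)))
  sp <- scoring_params()
  idx <- build_index(donor, sp, db_class = "bacterial")
  win <- window_scaffolds(scaf)
  iv <- scan_bacterial(scaf, win, idx, sp)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$scaffold, "sc")
  expect_equal(c(iv$start, iv$end), c(2200L, 2600L))
  expect_equal(iv$taxon, "donor_X")
})

test_that("the join rule is strictly less than the gap", {
  # gap exactly 50: NOT joined; gap 49: joined
  iv <- mk_iv("s", c(0L, 150L), c(100L, 300L))
  j50 <- join_intervals(iv, gap = 50L)
  expect_equal(nrow(j50), 2L)
  iv2 <- mk_iv("s", c(0L, 149L), c(100L, 300L))
  j49 <- join_intervals(iv2, gap = 50L)
  expect_equal(nrow(j49), 1L)
  expect_equal(c(j49$start, j49$end), c(0L, 300L))
  expect_equal(j49$n_windows, 2L)
})

test_that("joining is transitive, order-invariant, and idempotent", {
  set.seed(31)
  # random fragments on two scaffolds
  iv <- mk_iv(sample(c("s1", "s2"), 40, TRUE),
              start <- sample(0:5000, 40), start + sample(20:200, 40, TRUE),
              bitscore = runif(40, 50, 500))
  j1 <- join_intervals(iv, gap = 50L)
  # order invariance
  j2 <- join_intervals(iv[sample(nrow(iv)), ], gap = 50L)
  expect_equal(j1, j2)
  # idempotence (fixpoint)
  expect_equal(join_intervals(j1, gap = 50L), j1)
  # transitivity: a chain of 10-bp pieces 20 bp apart collapses to one
  chain <- mk_iv("c", seq(0L, 300L, by = 30L), seq(10L, 310L, by = 30L))
  expect_equal(nrow(join_intervals(chain, gap = 50L)), 1L)
  # merged metadata comes from the best-scoring part
  two <- mk_iv("s", c(0L, 20L), c(10L, 40L), taxon = c("A", "B"),
               bitscore = c(60, 80))
  m <- join_intervals(two, gap = 50L)
  expect_equal(m$taxon, "B")
  expect_equal(m$bitscore, 80)
})

test_that("the length filter keeps >= 100 bp inclusively", {
  iv <- mk_iv("s", c(0L, 500L, 1000L), c(99L, 600L, 1101L))
  cand <- length_filter(iv, min_len = 100L)
  expect_equal(cand$length, c(100L, 101L))
  expect_equal(cand$candidate_id, c("s:500-600", "s:1000-1101"))
})

test_that("the counter-screen removes animal-dominated intervals only", {
  iv <- mk_iv("s", c(0L, 1000L), c(500L, 1500L), bitscore = c(200, 200))
  anim <- data.frame(scaffold = "s", start = 0L, end = 500L,
                     bitscore = 300, evalue = 1e-30, stringsAsFactors = FALSE)
  kept <- counter_screen(iv, anim, scan_params())
  expect_equal(kept$start, 1000L)

  # weaker animal evidence does not veto under bacterial_gt_animal
  anim_weak <- transform(anim, bitscore = 100)
  expect_equal(nrow(counter_screen(iv, anim_weak, scan_params())), 2L)
  # ... but any overlap vetoes under absent_animal
  kept2 <- counter_screen(iv, anim_weak,
                          scan_params(counter_rule = "absent_animal"))
  expect_equal(kept2$start, 1000L)
  # animal hits above the E-value cutoff are ignored entirely
  anim_bad_e <- transform(anim, evalue = 1)
  expect_equal(nrow(counter_screen(iv, anim_bad_e, scan_params())), 2L)
  # a tie in bit score counts as animal evidence (bacterial must exceed)
  anim_tie <- transform(anim, bitscore = 200)
  expect_equal(counter_screen(iv, anim_tie, scan_params())$start, 1000L)
})

test_that("a grazing animal hit below the overlap fraction does not veto", {
  iv <- mk_iv("s", 1000L, 1400L, bitscore = 200)
  graze <- data.frame(scaffold = "s", start = 0L, end = 1002L,
                      bitscore = 500, evalue = 1e-40, stringsAsFactors = FALSE)
  expect_equal(nrow(counter_screen(iv, graze, scan_params())), 1L)
  # with the fraction set to zero, any overlap counts
  expect_equal(nrow(counter_screen(iv, graze,
                                   scan_params(counter_min_overlap = 0))), 0L)
})

test_that("an implant split across a window boundary joins to full length", {
  # 600-bp exact donor fragment centred on the boundary between tiles 1/2
  set.seed(32)
  donor <- c(donor_X = rand_dna(4000))
  frag <- substr(donor, 2001, 2600)
  scaf <- c(sc = paste0(rand_dna(700), frag, rand_dna(900)))
  sp <- scoring_params()
  bi <- build_index(donor, sp, db_class = "bacterial")
  ai <- build_index(c(tx = rand_dna(1000)), sp, db_class = "animal")
  cand <- run_scan(scaf, bi, ai)
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$start, cand$end), c(700L, 1300L))
  expect_equal(cand$genus, "donor_X")
  expect_gte(cand$n_windows, 2L)
})

test_that("run_scan excludes bacterial-called scaffolds from candidates", {
  set.seed(33)
  donor <- c(donor_X = rand_dna(3000))
  contam <- unname(substr(donor, 1, 2000))
  scaf <- c(host_sc = paste0(rand_dna(500), substr(donor, 2201, 2500),
                             rand_dna(500)),
            contam_sc = contam)
  sp <- scoring_params()
  bi <- build_index(donor, sp, db_class = "bacterial")
  ai <- build_index(c(tx = rand_dna(1000)), sp, db_class = "animal")
  calls <- data.frame(scaffold = c("host_sc", "contam_sc"),
                      call = c("ambiguous", "bacterial"),
                      stringsAsFactors = FALSE)
  cand <- run_scan(scaf, bi, ai, calls = calls)
  expect_true(all(cand$scaffold == "host_sc"))
  cand_all <- run_scan(scaf, bi, ai)
  expect_true("contam_sc" %in% cand_all$scaffold)
})

test_that("scanning simulated study-like data recovers implants", {
  cfg <- tiny_config(seed = 34)
  sim <- simulate_screen_inputs(cfg)
  res <- screen_simulation(sim)
  rs <- recovery_stats(res$candidates, sim$truth$implants)
  expect_equal(rs$sensitivity, 1)
  expect_equal(rs$n_spurious, 0L)
  # candidate boundaries agree with the truth within one window
  for (i in seq_len(nrow(sim$truth$implants))) {
    tr <- sim$truth$implants[i, ]
    ov <- res$candidates[res$candidates$scaffold == tr$scaffold &
                           res$candidates$start < tr$end &
                           tr$start < res$candidates$end, ]
    expect_equal(nrow(ov), 1L)
    expect_lte(abs(ov$start - tr$start), 50)
    expect_lte(abs(ov$end - tr$end), 50)
    expect_equal(ov$genus, tr$taxon)
  }
})

test_that("recovery is weakly monotone in implant divergence", {
  sens_at <- function(d) {
    mean(vapply(1:3, function(s) {
      cfg <- tiny_config(seed = 40 + s, divergence = d)
      sim <- simulate_screen_inputs(cfg)
      res <- screen_simulation(sim)
      recovery_stats(res$candidates, sim$truth$implants)$sensitivity
    }, numeric(1)))
  }
  s <- vapply(c(0, 0.05, 0.10, 0.20), sens_at, numeric(1))
  expect_true(all(diff(s) <= 1e-9))   # never increases with divergence
  expect_equal(s[1], 1)               # perfect at zero divergence
})
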