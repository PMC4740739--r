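test_that("config validation names the offending field", {
  expect_error(simulation_config(host_gc = 1.5), "host_gc")
  expect_error(simulation_config(implant_length_min = 0), "implant_length_min")
  expect_error(simulation_config(divergence = -0.1), "divergence")
  expect_error(simulation_config(pair_insert_mean = 150, read_length = 100),
               "pair_insert_mean")
  expect_error(simulation_config(n_contaminant_scaffolds = 5, n_donor_taxa = 3),
               "n_contaminant_scaffolds")
})

test_that("host simulation is deterministic with forced lengths and GC", {
  cfg <- simulation_config(seed = 1, n_host_scaffolds = 1,
                           host_scaffold_length = 10000, host_gc = 0.5)
  h1 <- simulate_host(cfg)
  h2 <- simulate_host(cfg)
  expect_equal(length(h1), 1L)
  expect_equal(Biostrings::width(h1), 10000L)
  expect_identical(as.character(h1), as.character(h2))

  # GC of a 100-kb scaffold within 4 binomial sd of the target
  cfg2 <- simulation_config(seed = 3, n_host_scaffolds = 1,
                            host_scaffold_length = 100000, host_gc = 0.35)
  h <- simulate_host(cfg2)
  gc <- sum(Biostrings::alphabetFrequency(h[[1]])[c("C", "G")]) / 100000
  expect_gt(gc, 0.33)
  expect_lt(gc, 0.37)
})

test_that("donors are labelled, reproducible, and unalignable to the host", {
  cfg <- simulation_config(seed = 2, n_donor_taxa = 3)
  d1 <- simulate_donors(cfg)
  expect_equal(length(d1), 3L)
  expect_equal(unname(scaffold_taxa(d1)),
               c("Arsenophonus", "Wolbachia", "Sodalis"))
  expect_identical(as.character(d1), as.character(simulate_donors(cfg)))

  # independent random 50-kb sequences never reach the E-value cutoff
  sp <- scoring_params()
  n_hits <- vapply(1:20, function(s) {
    cfg <- simulation_config(seed = 100 + s, n_host_scaffolds = 1,
                             host_scaffold_length = 50000,
                             n_donor_taxa = 1, donor_length = 50000,
                             n_contaminant_scaffolds = 0)
    idx <- build_index(simulate_donors(cfg), sp)
    nrow(search_scaffolds(simulate_host(cfg), idx, sp))
  }, numeric(1))
  expect_true(all(n_hits == 0))
})

test_that("implanting respects identity, decay rate, and conservation", {
  cfg0 <- tiny_config(n_implants = 0)
  host <- simulate_host(cfg0)
  donors <- simulate_donors(cfg0)
  res0 <- implant_lgts(host, donors, cfg0)
  expect_identical(as.character(res0$genome), as.character(host))
  expect_equal(nrow(res0$implants), 0L)

  # d = 0: implanted segment equals the donor substring exactly
  cfg1 <- tiny_config(seed = 5, n_implants = 1, implant_length_min = 500,
                      implant_length_max = 500, divergence = 0)
  res1 <- implant_lgts(simulate_host(cfg1), simulate_donors(cfg1), cfg1)
  tr <- res1$implants
  got <- substr(as.character(res1$genome[[tr$scaffold]]), tr$start + 1, tr$end)
  src <- substr(as.character(simulate_donors(cfg1)[[tr$donor]]),
                tr$donor_start + 1, tr$donor_end)
  expect_identical(got, src)

  # d = 0.05 on a 1,000-bp implant: Hamming distance in the binomial
  # central range [30, 70]
  cfg2 <- tiny_config(seed = 6, n_implants = 1, implant_length_min = 1000,
                      implant_length_max = 1000, divergence = 0.05)
  donors2 <- simulate_donors(cfg2)
  res2 <- implant_lgts(simulate_host(cfg2), donors2, cfg2)
  tr <- res2$implants
  got <- strsplit(substr(as.character(res2$genome[[tr$scaffold]]),
                         tr$start + 1, tr$end), "")[[1]]
  src <- strsplit(substr(as.character(donors2[[tr$donor]]),
                         tr$donor_start + 1, tr$donor_end), "")[[1]]
  ham <- sum(got != src)
  expect_gte(ham, 30)
  expect_lte(ham, 70)
  expect_equal(tr$divergence, ham / 1000)

  # conservation: genome length = host length + sum of implant lengths
  cfg3 <- tiny_config(seed = 7)
  host3 <- simulate_host(cfg3)
  res3 <- implant_lgts(host3, simulate_donors(cfg3), cfg3)
  expect_equal(sum(Biostrings::width(res3$genome)),
               sum(Biostrings::width(host3)) +
                 sum(res3$implants$end - res3$implants$start))

  # truth intervals lie within scaffold bounds and are disjoint per scaffold
  for (sc in unique(res3$implants$scaffold)) {
    tr <- res3$implants[res3$implants$scaffold == sc, ]
    tr <- tr[order(tr$start), ]
    expect_true(all(tr$start >= 0 & tr$end <= Biostrings::width(res3$genome[sc])))
    if (nrow(tr) > 1) expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)]))
  }
})

test_that("truth intervals recover their donor as best hit at moderate decay", {
  cfg <- tiny_config(seed = 8, divergence = 0.10)
  donors <- simulate_donors(cfg)
  res <- implant_lgts(simulate_host(cfg), donors, cfg)
  sp <- scoring_params()
  idx <- build_index(donors, sp, db_class = "bacterial")
  for (i in seq_len(nrow(res$implants))) {
    tr <- res$implants[i, ]
    seg <- substr(as.character(res$genome[[tr$scaffold]]), tr$start + 1, tr$end)
    h <- search_homology(seg, idx, sp)
    expect_gt(nrow(h), 0)
    expect_equal(h$taxon[1], tr$taxon)
  }
})

test_that("contaminant scaffolds append and align back to their donor", {
  cfg0 <- tiny_config(n_contaminant_scaffolds = 0)
  host <- simulate_host(cfg0)
  donors <- simulate_donors(cfg0)
  res0 <- add_contaminants(host, donors, cfg0)
  expect_identical(names(res0$genome), names(host))

  cfg2 <- tiny_config(seed = 9, n_contaminant_scaffolds = 2,
                      n_donor_taxa = 3)
  res2 <- add_contaminants(host, donors, cfg2)
  expect_equal(length(res2$genome), length(host) + 2L)
  expect_equal(nrow(res2$contaminants), 2L)

  sp <- scoring_params()
  idx <- build_index(donors, sp)
  for (i in seq_len(nrow(res2$contaminants))) {
    sc <- res2$contaminants$scaffold[i]
    h <- search_homology(as.character(res2$genome[[sc]]), idx, sp)
    expect_equal(h$taxon[1], res2$contaminants$taxon[i])
    cov <- (h$qend[1] - h$qstart[1]) / Biostrings::width(res2$genome[sc])
    expect_gte(cov, 0.95)
  }
})

test_that("pair simulation matches its Poisson junction-coverage model", {
  cfg0 <- tiny_config(pair_depth = 0)
  sim0 <- implant_lgts(simulate_host(cfg0), simulate_donors(cfg0), cfg0)
  expect_equal(nrow(simulate_pairs(sim0$genome, sim0$implants, cfg0)), 0L)

  cfg <- tiny_config(seed = 10, n_implants = 1, implant_length_min = 1500,
                     implant_length_max = 1500, pair_depth = 30)
  sim <- implant_lgts(simulate_host(cfg), simulate_donors(cfg), cfg)
  pairs <- simulate_pairs(sim$genome, sim$implants, cfg)
  expect_true(all(pairs$scaffold %in% names(sim$genome)))
  expect_true(all(pairs$m1_end - pairs$m1_start == cfg$read_length))

  # bridging pairs at the left junction: one mate strictly left, one
  # strictly right; lambda = depth * (insert - 2r) / insert
  j <- sim$implants$start[1]
  bridging <- sum(pairs$m1_end <= j & pairs$m2_start >= j)
  lambda <- cfg$pair_depth * (cfg$pair_insert_mean - 2 * cfg$read_length) /
    cfg$pair_insert_mean
  lo <- qpois(0.005, lambda); hi <- qpois(0.995, lambda)
  expect_gte(bridging, lo)
  expect_lte(bridging, hi)
})

test_that("expression tracks follow the condition-A-only design and round-trip", {
  cfg0 <- tiny_config(expressed_fraction = 0)
  sim0 <- implant_lgts(simulate_host(cfg0), simulate_donors(cfg0), cfg0)
  cov0 <- simulate_expression(sim0$genome, sim0$implants, cfg0)
  expect_equal(nrow(cov0$condA), 0L)
  expect_equal(nrow(cov0$condB), 0L)

  cfg <- tiny_config(seed = 11, expressed_fraction = 1, expression_depth = 50)
  sim <- implant_lgts(simulate_host(cfg), simulate_donors(cfg), cfg)
  cov <- simulate_expression(sim$genome, sim$implants, cfg)
  expect_equal(nrow(cov$condA), nrow(sim$implants))
  expect_true(all(cov$condA$value == 50))

  # written bedGraph re-read is value-identical
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph(cov$condA, f)
  back <- read_bedgraph(f)
  expect_equal(back[order(back$scaffold, back$start), ],
               cov$condA[order(cov$condA$scaffold, cov$condA$start), ],
               ignore_attr = TRUE)
})

test_that("the composed simulation is byte-deterministic", {
  cfg <- tiny_config(seed = 12)
  s1 <- simulate_screen_inputs(cfg)
  s2 <- simulate_screen_inputs(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$pairs, s2$pairs)
  expect_identical(s1$coverage$condA, s2$coverage$condA)
})
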