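test_that("reference generation is seed-deterministic with valid ground truth", {
  cfg <- sim_config(n_references = 2, length_range = c(100L, 100L), seed = 42)
  g1 <- generate_references(cfg)
  g2 <- generate_references(cfg)
  expect_identical(g1, g2)
  expect_equal(nchar(g1$references$residues), c(100L, 100L))

  # every site is an in-range first-G of a motif occurrence
  for (k in seq_len(nrow(g1$truth))) {
    row <- g1$truth[k, ]
    res <- g1$references$residues[g1$references$id == row$reference_id]
    expect_gte(row$position, 1L)
    expect_lt(row$position, nchar(res))
    expect_equal(substr(res, row$position, row$position + 2L), "TGG")
  }
})

test_that("spontaneous motif counts match the L/64 uniform expectation", {
  cfg <- sim_config(n_references = 200, length_range = c(500L, 500L),
                    seed = 99)
  g <- generate_references(cfg)
  counts <- as.numeric(table(factor(g$truth$reference_id,
                                    levels = g$references$id)))
  expected <- (500 - 2) / 64
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
  expect_false(any(g$truth$planted))
})

test_that("coverage profiles follow the 5'-end box-convolution model", {
  # no background, one site, reads span the whole reference -> step profile
  cfg <- sim_config(background_rate = 0, signal_rate = 500,
                    cleavage_probability = 1, read_length = 500L, seed = 5)
  # (plus the constant intact-end plateau contributed by position 0)
  prof <- simulate_cleavage_profile(80L, sites = 40L, cfg, seed = 5)
  expect_true(all(prof[1:40] == prof[1]))
  expect_true(all(prof[41:80] == prof[41]))
  expect_gt(prof[41], prof[1])

  # zero rates: no cleavage, no background, no intact ends -> all zero
  cfg0 <- sim_config(signal_rate = 0, background_rate = 0, seed = 5)
  prof0 <- simulate_cleavage_profile(60L, sites = integer(0), cfg0, seed = 5)
  expect_true(all(prof0 == 0))

  # depth equals direct convolution of the regenerated end counts with a box
  cfg2 <- sim_config(read_length = 25L, seed = 31)
  sites <- c(50L, 120L)
  prof2 <- simulate_cleavage_profile(200L, sites, cfg2, seed = 31)
  ends <- local({
    set.seed(31)
    lambda <- rep(cfg2$background_rate, 200)
    lambda[sites + 1] <- cfg2$signal_rate * cfg2$cleavage_probability
    e <- rpois(200, lambda)
    e[1] <- e[1] + rpois(1, cfg2$signal_rate)
    e
  })
  oracle <- vapply(1:200, function(n)
    sum(ends[max(1, n - 24):n]), numeric(1))
  expect_equal(as.numeric(prof2), oracle)
})

test_that("identical config and seed give byte-identical experiment files", {
  cfg <- sim_config(n_references = 2, length_range = c(200L, 400L), seed = 13)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  s1 <- simulate_cleavage_experiment(cfg, out_dir = d1)
  s2 <- simulate_cleavage_experiment(cfg, out_dir = d2)
  for (f in names(s1$files)) {
    expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]))
  }
  # written coverage reads back as the in-memory profiles
  refs <- read_fasta(s1$files[["refs"]], alphabet = "RNA")
  expect_identical(read_depth_table(s1$files[["coverage"]], refs),
                   s1$profiles)
})

test_that("CDS generation labels enrichment and degenerates cleanly", {
  plain <- generate_cds_set(n_records = 30, enriched_fraction = 0,
                            seed = 2)
  expect_false(any(plain$enriched))

  # multiplier 1: enriched and background motif densities indistinguishable
  flat <- generate_cds_set(n_records = 500, enriched_fraction = 0.5,
                           enrichment_multiplier = 1, seed = 17)
  dens <- vapply(flat$residues, count_motif, integer(1), USE.NAMES = FALSE) /
    (nchar(flat$residues) - 2)
  expect_gt(t.test(dens[flat$enriched], dens[!flat$enriched])$p.value, 0.01)

  # multiplier 2: enriched records carry about twice the expected density
  boosted <- generate_cds_set(n_records = 200, enriched_fraction = 0.5,
                              enrichment_multiplier = 2, seed = 17)
  dens2 <- vapply(boosted$residues, count_motif, integer(1),
                  USE.NAMES = FALSE) / (nchar(boosted$residues) - 2)
  ratio <- mean(dens2[boosted$enriched]) / mean(dens2[!boosted$enriched])
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})
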