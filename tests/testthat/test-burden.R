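test_that("composition probability is the product of motif-letter frequencies", {
  expect_equal(composition_probability("TGG"), (1 / 3) * (2 / 3)^2)
  expect_equal(composition_probability("AAAA"), 0)
  expect_equal(composition_probability("ACGT"), 1 / 64)
  # N excluded from numerator and denominator
  expect_equal(composition_probability("ACGTNNNN"), 1 / 64)
  expect_error(composition_probability("NNN"), "no A/C/G/T")
})

test_that("motif counting is overlapping, exact, and N-safe", {
  expect_equal(count_motif("TGGTGG"), 2L)
  expect_equal(count_motif("TGGG"), 1L)
  expect_equal(count_motif("TGNTGG"), 1L)   # N window never matches
  expect_equal(count_motif("AAA", "AA"), 2L)  # overlap for self-overlapping motif
  expect_error(count_motif("TG"), "shorter than motif")

  set.seed(12)
  seqres <- random_dna(1000)
  naive <- sum(vapply(1:998, function(s) substr(seqres, s, s + 2) == "TGG",
                      logical(1)))
  expect_equal(count_motif(seqres), naive)
})

test_that("binomial tail handles landmarks and argument errors", {
  expect_equal(binomial_tail(3, 0.5, 2), 0.5)
  expect_equal(binomial_tail(1711, 0.3, 0), 1)
  expect_equal(binomial_tail(10, 0, 3), 0)
  expect_equal(binomial_tail(10, 1, 10), 1)
  expect_error(binomial_tail(10, 1.2, 3), "p must be")
  expect_error(binomial_tail(10, 0.5, 11), "between 0 and trials_n")
})

test_that("binomial tail is monotone in K and its masses telescope to 1", {
  n <- 120; p <- 0.07
  tails <- vapply(0:n, function(k) binomial_tail(n, p, k), numeric(1))
  expect_true(all(diff(tails) <= 0))
  strict <- tails > 0 & tails < 1
  expect_true(all(diff(tails)[strict[-1]] < 0))
  # P(K) - P(K+1) = mass at K; total mass telescopes to P(0) = 1
  mass <- c(-diff(tails), tails[n + 1])
  expect_equal(sum(mass), 1, tolerance = 1e-12)
  expect_equal(mass, dbinom(0:n, n, p), tolerance = 1e-12)
})

test_that("deep tails agree with the incomplete-beta route to 1e-9 relative", {
  cases <- list(c(9193, 89.43 / 9193, 157), c(5000, 1e-3, 40),
                c(200, 0.02, 30), c(1711, 23.91 / 1711, 52))
  for (cs in cases) {
    mine <- binomial_tail(cs[1], cs[2], cs[3])
    ref <- pbinom(cs[3] - 1, cs[1], cs[2], lower.tail = FALSE)
    expect_lt(abs(mine - ref) / ref, 1e-9)
  }
})

test_that("burden_from_params recovers p = E/(L-2) and is internally consistent", {
  L <- 1500; p <- 0.015; K <- 40
  E <- p * (L - 2)
  expect_equal(burden_from_params(L, E, K), binomial_tail(L - 2, p, K))
  expect_error(burden_from_params(1500, 1600, 10))
})

test_that("scan_cds_set ranks motif-stuffed records first and is consistent", {
  set.seed(8)
  rich <- paste0(strrep("TGG", 40), random_dna(300))
  free <- gsub("TGG", "TAG", random_dna(400), fixed = TRUE)
  records <- data.frame(id = c("plain", "rich"), description = "",
                        residues = c(free, rich), symbol = "", product = "",
                        stringsAsFactors = FALSE)
  out <- scan_cds_set(records)
  expect_equal(out$id[1], "rich")
  expect_equal(out$rank, 1:2)
  expect_equal(out$P[out$id == "plain"][out$actual_K[out$id == "plain"] == 0],
               rep(1, sum(out$actual_K[out$id == "plain"] == 0)))
  # stored E agrees with p * (L - 2)
  expect_equal(out$expected_E, out$p * (out$length_L - 2), tolerance = 1e-9)
  expect_equal(out$actual_K,
               vapply(out$id, function(i)
                 count_motif(records$residues[records$id == i]), integer(1),
                 USE.NAMES = FALSE))

  single <- scan_cds_set(records[1, , drop = FALSE])
  expect_equal(single$rank, 1L)
})

test_that("published parameter replay reproduces ranking structure", {
  rep <- burden_from_table(published_params())
  expect_equal(rep$rank, seq_len(nrow(rep)))
  expect_true(all(diff(rep$P) >= 0))
  top10 <- rep$symbol[rep$rank <= 10]
  expect_true(all(c("hao1", "hao2", "hao3", "rbcL") %in% top10))
})

test_that("fraction_with_motif counts presence, not abundance", {
  recs <- data.frame(id = c("a", "b"), description = "",
                     residues = c("TGGAAA", "AAAAAA"), stringsAsFactors = FALSE)
  expect_equal(fraction_with_motif(recs), 0.5)
  none <- data.frame(id = "a", description = "", residues = "ACACAC",
                     stringsAsFactors = FALSE)
  expect_equal(fraction_with_motif(none), 0)
  expect_error(fraction_with_motif(recs[0, , drop = FALSE]), "empty")
})

test_that("read_cds_fasta parses symbol= and product= key-values", {
  fa <- write_tmp_fasta(c(">g1 symbol=hao product=Hydroxylamine_oxidoreductase",
                          "ATGTGGTAA", ">g2", "ATGAAATAA"))
  recs <- read_cds_fasta(fa)
  expect_equal(recs$symbol, c("hao", ""))
  expect_equal(recs$product[1], "Hydroxylamine oxidoreductase")
})
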