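test_that("tandem pair detection enumerates all (start, spacer) matches", {
  p <- find_tandem_pairs("GATAAAGAT")
  expect_equal(nrow(p), 1L)
  expect_equal(p$orientation, "GG")
  expect_equal(p$spacer, 3L)

  p <- find_tandem_pairs("GATATC")
  expect_equal(p$orientation, "GA")
  expect_equal(p$spacer, 0L)

  p <- find_tandem_pairs("GATGATGAT")
  expect_equal(nrow(p), 3L)
  expect_equal(p[, c("first_start", "spacer")],
               data.frame(first_start = c(0L, 0L, 3L),
                          spacer = c(0L, 3L, 0L)))

  # divergent ATC..GAT arrangement only counted on request
  expect_equal(nrow(find_tandem_pairs("ATCGAT")), 0L)
  d <- find_tandem_pairs("ATCGAT", include_divergent = TRUE)
  expect_equal(d$orientation, "AG")
})

test_that("pair counts match the brute-force oracle on random 200-mers", {
  set.seed(77)
  for (i in 1:1000) {
    seq <- random_dna(200)
    got <- tandem_counts_from_pairs(find_tandem_pairs(seq))
    want <- oracle_tandem_counts(seq)
    expect_identical(got$GG, want$GG)
    expect_identical(got$GA, want$GA)
  }
})

test_that("pair counts are invariant under reverse complement", {
  set.seed(13)
  rc <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  }
  for (i in 1:200) {
    seq <- random_dna(120)
    a <- tandem_counts_from_pairs(find_tandem_pairs(seq))
    b <- tandem_counts_from_pairs(find_tandem_pairs(rc(seq)))
    expect_identical(a$GG, b$GG)
    expect_identical(a$GA, b$GA)
  }
})

test_that("analytic expectation gives the two-fold same-strand excess", {
  u <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  expect_equal(expected_pair_probability(u, "GA"), 1 / 4096)
  expect_equal(expected_pair_probability(u, "GG"), 2 / 4096)
  # skewed composition: GG still sums its two plus-strand patterns
  b <- c(A = 0.3, C = 0.2, G = 0.3, T = 0.2)
  p_gat <- 0.3 * 0.3 * 0.2
  p_atc <- 0.3 * 0.2 * 0.2
  expect_equal(expected_pair_probability(b, "GA"), p_gat * p_atc)
  expect_equal(expected_pair_probability(b, "GG"), p_gat^2 + p_atc^2)
})

test_that("empirical pair rates on an iid genome match the expectation", {
  cfg <- sim_config(seed = 5, genome_length = 1000000L,
                    n_peaks = c(G1 = 0L, G2 = 0L, G3 = 0L))
  genome <- make_genome(cfg)
  pairs <- find_tandem_pairs(unclass(genome)[[1L]])
  n_pos <- 1e6 * 11  # (start, spacer) combinations, edge effects negligible
  for (o in c("GG", "GA")) {
    obs <- sum(pairs$orientation == o)
    p <- expected_pair_probability(cfg$base_freq, o)
    expect_lt(abs(obs - n_pos * p), 4 * sqrt(n_pos * p * (1 - p)))
  }
  ratio <- sum(pairs$orientation == "GG") / sum(pairs$orientation == "GA")
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("spacing table aggregates pair and locus counts per class", {
  fx <- single_peak_fixture("GATAAAGAT", class_label = "G1")
  tab <- spacing_table(fx$peaks, fx$genome)
  expect_equal(tab$counts["G1", "GG", "3"], 1L)
  expect_equal(tab$loci_with_pair["G1", "GG", "3"], 1L)
  expect_equal(sum(tab$counts), 1L)

  fx <- single_peak_fixture("GATGATGAT", class_label = "G3")
  tab <- spacing_table(fx$peaks, fx$genome)
  expect_equal(tab$counts["G3", "GG", "1"], 0L)
  expect_equal(tab$counts["G3", "GG", "0"], 2L)
  expect_equal(tab$loci_with_pair["G3", "GG", "0"], 1L)
  expect_true(all(tab$counts >= tab$loci_with_pair))

  empty <- spacing_table(fx$peaks[0, ], fx$genome)
  expect_equal(sum(empty$counts), 0L)
})

test_that("random windows respect exclusions, N runs and the seed", {
  g <- as_genome(c(c1 = random_dna(10000, seed = 21)))
  w <- sample_random_windows(g, 5, 200, seed = 3)
  expect_equal(nrow(w), 5L)
  expect_true(all(w$start >= 0 & w$end <= 10000))
  expect_identical(w, sample_random_windows(g, 5, 200, seed = 3))
  expect_false(identical(w, sample_random_windows(g, 5, 200, seed = 4)))

  # exclusion covering all but one 200 bp stretch forces the placement
  excl <- data.frame(chrom = "c1", start = c(0L, 700L),
                     end = c(500L, 10000L))
  w <- sample_random_windows(g, 8, 200, exclude = excl, seed = 1)
  expect_true(all(w$start == 500L))

  # windows never cover an N
  seq <- paste0(strrep("A", 300), "N", strrep("A", 300))
  gn <- as_genome(c(c1 = seq))
  w <- sample_random_windows(gn, 50, 100, seed = 2)
  expect_true(all(w$end <= 300 | w$start >= 301))

  expect_error(sample_random_windows(gn, 1, 700), "no valid")
})

test_that("Monte Carlo p-values hit their boundary cases", {
  # no pairs anywhere: observed 0 is minimal, p must be exactly 1
  g <- as_genome(c(c1 = strrep("C", 5000)))
  pk <- data.frame(chrom = "c1", start = 100L, end = 300L)
  mc <- monte_carlo_enrichment(pk, g, R = 99, seed = 1,
                               exclude_peaks = FALSE)
  expect_equal(mc$observed, 0L)
  expect_equal(mc$empirical_p, 1)

  # all pairs concentrated in the peak window: observed beats every
  # replicate, p = 1 / (R + 1)
  seq <- paste0(strrep("C", 100), strrep("GAT", 60), strrep("C", 4000))
  g <- as_genome(c(c1 = seq))
  mc <- monte_carlo_enrichment(pk, g, R = 999, seed = 1)
  expect_gt(mc$observed, 0L)
  expect_true(all(mc$replicate_counts < mc$observed))
  expect_equal(mc$empirical_p, 1 / 1000)
})

test_that("Monte Carlo p-values are super-uniform under the null", {
  cfg <- sim_config(seed = 11, genome_length = 200000L,
                    n_peaks = c(G1 = 0L, G2 = 0L, G3 = 0L))
  genome <- make_genome(cfg)
  ps <- vapply(1:200, function(r) {
    wins <- sample_random_windows(genome, 50, 200, seed = 1000 + r)
    monte_carlo_enrichment(wins, genome, "any", R = 99, seed = 5000 + r,
                           exclude_peaks = FALSE)$empirical_p
  }, 0)
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / 200)
  expect_lte(mean(ps <= 0.05), bound)
})

test_that("class contrasts use the uncorrected 2x2 chi-squared", {
  cc <- chisq_class_compare(25, 100, 25, 100)
  expect_equal(cc$statistic, 0)
  expect_equal(cc$p_value, 1)
  expect_equal(chisq_class_compare(10, 20, 10, 20)$statistic, 0)

  cc <- chisq_class_compare(30, 100, 10, 100)
  expect_equal(cc$statistic, 12.5)
  expect_equal(cc$p_value, 4.07e-4, tolerance = 1e-3)

  expect_error(chisq_class_compare(0, 10, 0, 10), "degenerate")
})

test_that("per-spacer enrichment flags planted spacings", {
  uniform <- rep(40L, 11)
  enr <- spacer_enrichment(uniform, uniform)
  expect_equal(enr$fold, rep(1, 11))
  expect_true(all(enr$p_value > 0.9))

  planted <- c(rep(2L, 6), 120L, rep(2L, 4))  # mass at spacer 6
  enr <- spacer_enrichment(planted, uniform)
  expect_equal(enr$spacer[which.max(enr$fold)], 6L)
  expect_lt(enr$p_value[enr$spacer == 6], 1e-10)

  expect_warning(out <- spacer_enrichment(c(5L, rep(0L, 10)),
                                          rep(0L, 11)),
                 "degenerate")
  expect_true(all(out$p_value[!is.na(out$p_value)] >= 0))
})
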