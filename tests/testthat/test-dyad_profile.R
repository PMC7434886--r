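test_that("WGATAR scanning handles both strands and ambiguity", {
  h <- wgatar_hits("TGATAA")
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "+")
  expect_equal(h$matched, "TGATAA")

  h <- wgatar_hits("TTATCA")  # revcomp is TGATAA
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "-")
  expect_equal(h$matched, "TGATAA")

  expect_equal(nrow(wgatar_hits("CGATAA")), 0L)  # C is not W
  expect_equal(nrow(wgatar_hits("TGANA")), 0L)   # too short
  expect_equal(nrow(wgatar_hits("TGATNA")), 0L)  # N never matches
})

test_that("WGATAR scanning agrees with a regex oracle on random 60-mers", {
  set.seed(42)
  for (i in 1:1000) {
    seq <- random_dna(60)
    got <- wgatar_hits(seq)
    want <- oracle_wgatar(seq)
    expect_identical(got$start[got$strand == "+"], want$plus)
    expect_identical(got$start[got$strand == "-"], want$minus)
  }
})

test_that("closest motif minimizes distance to summit with left tie-break", {
  hits <- data.frame(chrom = "c", start = c(87, 101), end = c(93, 107),
                     strand = "+", matched = "TGATAA")
  # centers 90 and 104
  expect_equal(closest_motif(hits, 100)$start, 101)
  hits$start <- c(93, 101)  # centers 96 and 104: tie at distance 4
  expect_equal(closest_motif(hits, 100)$start, 93)
  expect_null(closest_motif(hits[0, ], 100))
})

test_that("profile accumulation bins offsets and honors strand flipping", {
  p <- accumulate_profile(500L, 500L, "+", K = 50L)
  expect_equal(p$counts[p$offsets == 0], 1L)
  expect_equal(sum(p$counts), 1L)

  p <- accumulate_profile(520L, 500L, "-", K = 50L,
                          orient_by_motif_strand = TRUE)
  expect_equal(p$counts[p$offsets == -20], 1L)

  p <- accumulate_profile(520L, 500L, "-", K = 50L,
                          orient_by_motif_strand = FALSE)
  expect_equal(p$counts[p$offsets == 20], 1L)

  # midpoints beyond +/-K are discarded and the count sum reflects it
  p <- accumulate_profile(c(449L, 451L, 550L, 552L), 500L, "+", K = 50L)
  expect_equal(sum(p$counts), 2L)
})

test_that("uniform midpoints give near-uniform per-offset counts", {
  K <- 50L
  set.seed(9)
  mids <- sample(450:550, 5000, replace = TRUE)
  p <- accumulate_profile(mids, 500L, "+", K = K)
  n <- 2L * K + 1L
  expected <- 5000 / n
  sigma <- sqrt(5000 * (1 / n) * (1 - 1 / n))
  expect_true(all(abs(p$counts - expected) < 4 * sigma))
})

test_that("control normalization is depth-invariant with hand-checked ratios", {
  prof <- function(counts) {
    structure(list(offsets = seq_along(counts) - 1L,
                   counts = as.integer(counts), n_loci = 1L),
              class = "dyad_profile")
  }
  s <- prof(c(5, 1, 3))
  expect_equal(normalize_profile(s, s)$ratio, rep(1, 3))
  # depth invariance is exact without the pseudocount and holds to within
  # the pseudocount's perturbation otherwise
  expect_equal(normalize_profile(prof(c(10, 2, 6)), s,
                                 pseudocount = 0)$ratio,
               rep(1, 3))
  expect_equal(normalize_profile(prof(c(10, 2, 6)), s)$ratio, rep(1, 3),
               tolerance = 0.15)

  n <- normalize_profile(prof(c(2, 0)), prof(c(1, 1)), pseudocount = 0.5)
  expect_equal(n$ratio, c((2.5 / 3) / (1.5 / 3), (0.5 / 3) / (1.5 / 3)))

  expect_error(normalize_profile(prof(c(0, 0)), prof(c(0, 0))),
               "degenerate")
})

test_that("Gaussian smoothing conserves mass and is symmetric", {
  x <- c(rep(0, 20), 1, rep(0, 20))
  expect_identical(smooth_profile(x, 0), x)
  y <- smooth_profile(x, 5)
  expect_equal(which.max(y), 21L)
  expect_equal(y[21 - (1:10)], y[21 + (1:10)], tolerance = 1e-12)

  set.seed(5)
  z <- runif(301) * 100
  expect_equal(sum(smooth_profile(z, 15)), sum(z), tolerance = 1e-9)
  # mass is conserved even when the kernel overhangs the boundary
  d <- c(1, rep(0, 30))
  expect_equal(sum(smooth_profile(d, 8)), 1, tolerance = 1e-9)

  expect_error(smooth_profile(x, -1), "sigma")
})

test_that("heatmap is log2 of the normalized ratio over +/-75", {
  prof <- function(counts, K = 80L) {
    structure(list(offsets = seq(-K, K), counts = as.integer(counts),
                   n_loci = 1L),
              class = "dyad_profile")
  }
  same <- prof(rep(7L, 161))
  hm <- build_heatmap(list(G1_pre = list(signal = same, control = same)))
  expect_equal(ncol(hm), 151L)
  expect_true(all(hm == 0))

  # doubling the central bin of the signal doubles its pseudocounted
  # proportion ratio; check against normalize_profile directly
  sig <- prof(c(rep(7L, 80), 14L, rep(7L, 80)))
  hm <- build_heatmap(list(g = list(signal = sig, control = same)))
  norm <- normalize_profile(restrict_profile(sig, 75L),
                            restrict_profile(same, 75L))
  expect_equal(unname(hm["g", ]), log2(norm$ratio))
})

test_that("class profiles anchor at the planted motif and recover dyads", {
  fx <- single_peak_fixture("TGATAA", class_label = "G1")
  # planted WGATAR occupies window center; its center is the summit
  summit <- fx$peaks$summit
  frags <- data.frame(chrom = "chr1",
                      start = c(summit - 94L, summit - 52L),
                      end = c(summit + 53L, summit + 95L))
  # midpoints: summit - 21 and summit + 21
  prof <- class_profiles(fx$genome, fx$peaks, frags, K = 50L)
  expect_named(prof, "G1")
  expect_equal(prof$G1$n_loci, 1L)
  expect_equal(prof$G1$offsets[prof$G1$counts > 0], c(-21L, 21L))
})

test_that("minus-strand anchors flip the offset axis in class profiles", {
  fx <- single_peak_fixture("TTATCA", class_label = "G2")
  summit <- fx$peaks$summit
  frags <- data.frame(chrom = "chr1", start = summit + 20L - 73L,
                      end = summit + 20L + 74L)  # midpoint summit + 20
  prof <- class_profiles(fx$genome, fx$peaks, frags, K = 50L)
  expect_equal(prof$G2$offsets[prof$G2$counts > 0], -20L)
  prof <- class_profiles(fx$genome, fx$peaks, frags, K = 50L,
                         orient_by_motif_strand = FALSE)
  expect_equal(prof$G2$offsets[prof$G2$counts > 0], 20L)
})
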