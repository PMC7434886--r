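test_that("superhelical location is a linear map from the dyad", {
  fr <- nuc_frame(dyad_index = 72L, wrap_length = 145L, period = 10.4)
  expect_equal(shl_of(72, fr), 0)
  expect_equal(shl_of(93, fr), 21 / 10.4)
  expect_equal(shl_of(15, fr), -57 / 10.4)
  expect_error(shl_of(145, fr), "outside")

  p <- seq(0, 134, by = 1)
  expect_equal(shl_of(p + 10.4, fr) - shl_of(p, fr), rep(1, length(p)))
})

test_that("groove face follows the half-integer-exposed convention", {
  expect_equal(groove_face(5.5)$face, "solvent_major")
  expect_equal(groove_face(5.0)$face, "histone_major")
  expect_equal(groove_face(0.0)$face, "histone_major")
  expect_equal(groove_face(-6.5)$face, "solvent_major")
  # boundary phase 0.25 is assigned to the histone face
  expect_equal(groove_face(5.25)$face, "histone_major")
  expect_equal(groove_face(5.26)$face, "solvent_major")

  s <- seq(-7, 7, by = 0.01)
  expect_identical(groove_face(s)$face, groove_face(s + 1)$face)
})

test_that("tandem geometry classification covers all categories", {
  fr <- nuc_frame()
  # spacer 6, first GAT center at the bp nearest SHL5.5 -> consecutive
  # solvent-exposed major grooves
  fs <- fr$dyad_index + as.integer(round(5.5 * fr$period)) - 1L
  cl <- classify_tandem_geometry(fs, 6L, fr)
  expect_equal(cl$category, "dual_exposed_consecutive")
  expect_equal(cl$delta_shl, 9 / 10.4)

  # spacer 3 (centers 6 bp apart): second center rotates onto the histone
  cl <- classify_tandem_geometry(fs, 3L, fr)
  expect_equal(cl$category, "one_buried")

  # both centers at integer SHLs
  fr10 <- nuc_frame(dyad_index = 70L, wrap_length = 145L, period = 10)
  cl <- classify_tandem_geometry(119L, 7L, fr10)  # centers at SHL 5 and 6
  expect_equal(cl$category, "both_buried")

  expect_error(classify_tandem_geometry(140L, 6L, fr), "outside")
})

test_that("the spacer-6 SHL5.5 classification is robust across periods", {
  for (period in seq(10.0, 10.6, by = 0.05)) {
    fr <- nuc_frame(period = period)
    fs <- fr$dyad_index + as.integer(round(5.5 * period)) - 1L
    cl <- classify_tandem_geometry(fs, 6L, fr)
    expect_equal(cl$category, "dual_exposed_consecutive",
                 info = paste("period", period))
  }
})

test_that("motif insertion lands the GAT center at the target SHL", {
  fr <- nuc_frame()
  tmpl <- make_widom601_synthetic(frame = fr)
  d <- design_insertion(tmpl, fr, 2, "SHL2x")
  expect_equal(nchar(d$sequence), nchar(tmpl))
  # first GAT center of AGATANCATCT at dyad + round(2 * period) = index 93
  expect_equal(substr(d$sequence, 93, 95), "GAT")
  expect_true(nrow(d$edits) > 0)
  # re-inserting over an identical region is a recorded no-op
  d2 <- design_insertion(d$sequence, fr, 2, "again")
  expect_equal(nrow(d2$edits), 0L)

  for (target in c(-4, -2.5, 1.3, 3, 5.5)) {
    dd <- design_insertion(tmpl, fr, target, "t")
    hits <- scan_gat(dd$sequence)
    shl <- shl_of(hits$start[hits$strand == "+"] + 1L, fr)
    expect_lt(min(abs(shl - target)), 0.05)
  }
  expect_error(design_insertion(tmpl, fr, 7, "off"), "bounds")
})

test_that("the rotational series yields five distinct named constructs", {
  fr <- nuc_frame()
  tmpl <- make_widom601_synthetic(frame = fr)
  ser <- design_insertion_series(tmpl, fr, 5)
  expect_named(ser, paste0("SHL5", letters[1:5]))
  seqs <- vapply(ser, `[[`, "", "sequence")
  expect_equal(length(unique(seqs)), 5L)
  expect_true(all(nchar(seqs) == nchar(tmpl)))
})

test_that("GAT knockout is minimal, clean and non-repeatable", {
  ko <- knockout_gat("AGATC", 1L)
  expect_equal(ko$sequence, "AGCTC")
  expect_equal(nrow(ko$edits), 1L)
  expect_false(grepl("GAT|ATC", ko$sequence))
  expect_error(knockout_gat(ko$sequence, 1L), "no GAT/ATC")

  # differential oracle: knocking out one GAT removes exactly the pairs
  # involving it
  seq <- "GGATTGGGGGGATTGGGGGCATC"
  before <- find_tandem_pairs(seq)
  target <- 10L  # second GAT
  after <- find_tandem_pairs(knockout_gat(seq, target)$sequence)
  involves <- before$first_start == target |
    (before$first_start + 3L + before$spacer) == target
  expect_equal(nrow(after), sum(!involves))
  expect_equal(after[, c("first_start", "spacer", "orientation")],
               before[!involves, c("first_start", "spacer", "orientation")],
               ignore_attr = TRUE)
})

test_that("the synthetic 601-style template is deterministic with three GATs", {
  t1 <- make_widom601_synthetic()
  expect_identical(t1, make_widom601_synthetic())
  expect_equal(nchar(t1), 145L)
  expect_equal(nrow(wgatar_hits(t1)), 0L)
  sg <- scan_gat(t1)
  lab <- shl_label(sg$start + 1L, nuc_frame())
  expect_true(all(c(-3, 2) %in% lab))
})

test_that("the synthetic SHL5e construct has the described GAT layout", {
  fr <- nuc_frame()
  s5e <- design_shl5e(frame = fr)
  sg <- scan_gat(s5e$sequence)
  lab <- shl_label(sg$start + 1L, fr)
  expect_true(all(c(5, 5.5, 6.5) %in% lab))
  gf <- groove_face(shl_of(sg$start + 1L, fr))
  expect_equal(gf$face[lab == 5], "histone_major")
  expect_equal(gf$face[lab == 5.5], "solvent_major")
  expect_equal(gf$face[lab == 6.5], "solvent_major")
})
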