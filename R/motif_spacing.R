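# Tandem 5'-GAT-3' spacing statistics.
#
# A tandem pair is two GAT trinucleotides separated by a spacer of 0-10 bp.
# Orientation GG (same strand) covers the plus-strand patterns GAT.{x}GAT
# and ATC.{x}ATC; orientation GA (opposite strands, convergent) is
# GAT.{x}ATC. Scanning the plus strand for exactly these three patterns
# counts each physical pair once: the pattern set is closed under reverse
# complement. The divergent arrangement ATC.{x}GAT is not counted by
# default but can be enabled for exploration.

gat_triplet_starts <- function(seq, triplet) {
  m <- gregexpr(triplet, seq, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m) - 1L
}

# all (a in s1, b in s2) with b - a - 3 in [0, max_spacer]; returns
# data.frame(first_start, spacer)
pair_starts <- function(s1, s2, max_spacer) {
  if (length(s1) == 0L || length(s2) == 0L) {
    return(data.frame(first_start = integer(), spacer = integer()))
  }
  s2 <- sort(s2)
  lo <- findInterval(s1 + 3 - 0.5, s2)
  hi <- findInterval(s1 + 3 + max_spacer + 0.5, s2)
  n <- hi - lo
  keep <- n > 0L
  if (!any(keep)) {
    return(data.frame(first_start = integer(), spacer = integer()))
  }
  first <- rep(s1[keep], n[keep])
  second <- s2[sequence(n[keep], from = lo[keep] + 1L)]
  data.frame(first_start = first, spacer = second - first - 3L)
}

#' Find tandem GAT pairs in a window sequence
#'
#' Scans the plus strand for `GAT.{x}GAT`, `ATC.{x}ATC` (orientation GG) and
#' `GAT.{x}ATC` (orientation GA) for every spacer `x` in `spacer_range`.
#' Every matching start is reported; overlapping and nested matches all
#' count. N never matches.
#'
#' @param seq Window sequence over A, C, G, T, N.
#' @param spacer_range Integer vector `c(min, max)` of spacer lengths
#'   (default `c(0, 10)`).
#' @param include_divergent Also count the divergent `ATC.{x}GAT`
#'   arrangement as orientation `"AG"` (default `FALSE`).
#' @return Data frame with `first_start` (0-based, plus-strand frame),
#'   `spacer`, `orientation` (`"GG"`/`"GA"`/`"AG"`), `plus_pattern`; sorted
#'   by `(first_start, spacer)`.
#' @export
find_tandem_pairs <- function(seq, spacer_range = c(0L, 10L),
                              include_divergent = FALSE) {
  stopifnot(spacer_range[1L] >= 0L, spacer_range[2L] >= spacer_range[1L])
  gat <- gat_triplet_starts(seq, "GAT")
  atc <- gat_triplet_starts(seq, "ATC")
  max_sp <- spacer_range[2L]
  gg1 <- pair_starts(gat, gat, max_sp)
  gg2 <- pair_starts(atc, atc, max_sp)
  ga <- pair_starts(gat, atc, max_sp)
  res <- rbind(
    cbind(gg1, orientation = rep("GG", nrow(gg1)),
          plus_pattern = rep("GATNxGAT", nrow(gg1))),
    cbind(gg2, orientation = rep("GG", nrow(gg2)),
          plus_pattern = rep("ATCNxATC", nrow(gg2))),
    cbind(ga, orientation = rep("GA", nrow(ga)),
          plus_pattern = rep("GATNxATC", nrow(ga)))
  )
  if (include_divergent) {
    ag <- pair_starts(atc, gat, max_sp)
    res <- rbind(res, cbind(ag, orientation = rep("AG", nrow(ag)),
                            plus_pattern = rep("ATCNxGAT", nrow(ag))))
  }
  res <- res[res$spacer >= spacer_range[1L], , drop = FALSE]
  res <- res[order(res$first_start, res$spacer), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-class tandem-pair spacing table over peak windows
#'
#' Aggregates [find_tandem_pairs()] over every peak window: total pair
#' counts and the number of loci with at least one pair, per class,
#' orientation and spacer. Windows extending past a chromosome end are
#' clipped with a warning.
#'
#' @param peaks Validated peak data frame.
#' @param genome A `"genome"` object.
#' @param max_spacer Largest spacer considered (default 10).
#' @return List with 3-d arrays `counts` and `loci_with_pair`
#'   (class x orientation x spacer) and named vector `n_peaks`.
#' @export
spacing_table <- function(peaks, genome, max_spacer = 10L) {
  classes <- c("G1", "G2", "G3")
  orients <- c("GG", "GA")
  spacers <- 0:max_spacer
  dn <- list(classes, orients, as.character(spacers))
  counts <- array(0L, dim = c(3L, 2L, length(spacers)), dimnames = dn)
  loci <- array(0L, dim = c(3L, 2L, length(spacers)), dimnames = dn)
  lens <- genome_lengths(genome)
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    s <- p$start
    e <- p$end
    if (s < 0L || e > lens[[p$chrom]]) {
      warning("peak window clipped to chromosome bounds: ", p$id)
      s <- max(0L, s)
      e <- min(lens[[p$chrom]], e)
    }
    pairs <- find_tandem_pairs(genome_subseq(genome, p$chrom, s, e),
                               c(0L, max_spacer))
    if (nrow(pairs) == 0L) next
    for (o in orients) {
      sub <- pairs[pairs$orientation == o, , drop = FALSE]
      if (nrow(sub) == 0L) next
      tab <- table(factor(sub$spacer, levels = spacers))
      counts[p$class_label, o, ] <- counts[p$class_label, o, ] +
        as.integer(tab)
      loci[p$class_label, o, ] <- loci[p$class_label, o, ] +
        as.integer(tab > 0L)
    }
  }
  n_peaks <- vapply(classes, function(cl) sum(peaks$class_label == cl), 0L)
  list(counts = counts, loci_with_pair = loci, n_peaks = n_peaks)
}

#' Analytic per-position tandem-pair probability under an iid base model
#'
#' For base probabilities `p`, the convergent (GA) pattern GAT.{x}ATC has
#' per-position probability `pG pA pT * pA pT pC` (spacer bases free); the
#' same-strand (GG) class sums its two plus-strand patterns,
#' `(pG pA pT)^2 + (pA pT pC)^2`. Neither depends on the spacer length, and
#' under a uniform model the GG/GA ratio is exactly 2 — same-strand tandem
#' GATs are twice as probable as convergent ones.
#'
#' @param base_freq Named probabilities for A, C, G, T summing to 1.
#' @param orientation `"GG"` or `"GA"`.
#' @param spacer Spacer length (accepted for interface symmetry; the
#'   probability does not depend on it).
#' @return Per-position probability of a pair with that orientation and
#'   spacer.
#' @export
expected_pair_probability <- function(base_freq, orientation, spacer = 0L) {
  stopifnot(all(c("A", "C", "G", "T") %in% names(base_freq)),
            abs(sum(base_freq) - 1) < 1e-12, all(base_freq >= 0))
  p_gat <- base_freq[["G"]] * base_freq[["A"]] * base_freq[["T"]]
  p_atc <- base_freq[["A"]] * base_freq[["T"]] * base_freq[["C"]]
  switch(orientation,
         GA = p_gat * p_atc,
         GG = p_gat^2 + p_atc^2,
         stop("orientation must be GG or GA"))
}

# valid window start positions per chromosome: window fits, contains no N,
# and does not overlap any exclusion interval
valid_window_starts <- function(genome, window, exclude = NULL) {
  lens <- genome_lengths(genome)
  lapply(names(genome), function(ch) {
    L <- lens[[ch]]
    if (L < window) return(integer())
    ok <- rep(TRUE, L - window + 1L)
    # N mask: a start p is invalid if any N in [p, p+window)
    npos <- gat_triplet_starts(genome[[ch]], "N")
    if (length(npos)) {
      for (np in npos) {
        lo <- max(0L, np - window + 1L)
        hi <- min(L - window, np)
        if (hi >= lo) ok[(lo:hi) + 1L] <- FALSE
      }
    }
    if (!is.null(exclude)) {
      ex <- exclude[exclude$chrom == ch, , drop = FALSE]
      for (j in seq_len(nrow(ex))) {
        lo <- max(0L, ex$start[j] - window + 1L)
        hi <- min(L - window, ex$end[j] - 1L)
        if (hi >= lo) ok[(lo:hi) + 1L] <- FALSE
      }
    }
    which(ok) - 1L
  }) -> starts
  names(starts) <- names(genome)
  starts
}

#' Sample random genomic windows
#'
#' Windows are drawn uniformly (with replacement, so they may overlap each
#' other) over all placements that fit on a chromosome, contain no N, and do
#' not overlap the exclusion intervals — a self-contained equivalent of
#' shuffling peak windows to random genomic positions.
#'
#' @param genome A `"genome"` object.
#' @param n Number of windows.
#' @param window Window width in bp.
#' @param exclude Optional data frame of intervals (`chrom`, `start`,
#'   `end`) that windows must not overlap.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return Data frame of `n` intervals (`chrom`, `start`, `end`).
#' @export
sample_random_windows <- function(genome, n, window, exclude = NULL,
                                  seed = 1L) {
  starts <- valid_window_starts(genome, window, exclude)
  chrom_of <- rep(names(starts), lengths(starts))
  pos <- unlist(starts, use.names = FALSE)
  if (length(pos) == 0L) stop("no valid window placement exists")
  idx <- with_seed(seed, sample.int(length(pos), n, replace = TRUE))
  data.frame(chrom = chrom_of[idx], start = pos[idx],
             end = pos[idx] + as.integer(window))
}

# Pair index for fast window counting: for each footprint length L = 6 + x,
# the sorted plus-strand start positions (per chromosome) of all pairs with
# the requested orientation(s). A pair lies inside window [a, a + w) iff
# start >= a and start <= a + w - L.
build_pair_index <- function(genome, max_spacer = 10L,
                             orientation = c("any", "GG", "GA")) {
  orientation <- match.arg(orientation)
  lapply(names(genome), function(ch) {
    seq <- genome[[ch]]
    gat <- gat_triplet_starts(seq, "GAT")
    atc <- gat_triplet_starts(seq, "ATC")
    per_x <- lapply(0:max_spacer, function(x) {
      s <- integer()
      if (orientation %in% c("any", "GG")) {
        s <- c(s, gat[(gat + 3L + x) %in% gat], atc[(atc + 3L + x) %in% atc])
      }
      if (orientation %in% c("any", "GA")) {
        s <- c(s, gat[(gat + 3L + x) %in% atc])
      }
      sort(s)
    })
    names(per_x) <- as.character(0:max_spacer)
    per_x
  }) -> idx
  names(idx) <- names(genome)
  idx
}

# Vectorized pair counting over many windows against a pair index.
count_pairs_in_windows <- function(pair_index, windows, window_width) {
  total <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    sel <- windows$chrom == ch
    a <- windows$start[sel]
    idx <- pair_index[[ch]]
    cnt <- numeric(length(a))
    for (xs in names(idx)) {
      L <- 6L + as.integer(xs)
      s <- idx[[xs]]
      if (length(s) == 0L) next
      cnt <- cnt + (findInterval(a + window_width - L + 0.5, s) -
                      findInterval(a - 0.5, s))
    }
    total[sel] <- cnt
  }
  as.integer(total)
}

#' Monte Carlo enrichment test for tandem pairs in peak windows
#'
#' The observed statistic is the total tandem-pair count over all peak
#' windows. Each of the `R` null replicates recomputes the count over an
#' equal number of freshly sampled random windows (peak windows excluded).
#' The empirical p-value is `(1 + #(null >= observed)) / (1 + R)`, so it is
#' never zero and is exactly 1 when the observed count is minimal.
#'
#' @param peaks Validated peak data frame (their intervals are the windows).
#' @param genome A `"genome"` object.
#' @param orientation `"any"`, `"GG"` or `"GA"`.
#' @param R Number of null replicates (>= 99).
#' @param seed Integer seed.
#' @param max_spacer Largest spacer considered (default 10).
#' @param exclude_peaks Exclude the peak windows from the null sampling
#'   space (default `TRUE`, mirroring shuffle-style exclusion of the real
#'   peaks). Set `FALSE` when the "peaks" are themselves random windows
#'   (e.g. calibration studies), where exclusion would break
#'   exchangeability between observed and null window sets.
#' @return List with `observed`, `replicate_counts` (length `R`),
#'   `empirical_p`, `R`, `seed`.
#' @export
monte_carlo_enrichment <- function(peaks, genome, orientation = "any",
                                   R = 1000L, seed = 1L,
                                   max_spacer = 10L,
                                   exclude_peaks = TRUE) {
  stopifnot(R >= 99L)
  w <- unique(peaks$end - peaks$start)
  stopifnot(length(w) == 1L)
  idx <- build_pair_index(genome, max_spacer, orientation)
  observed <- sum(count_pairs_in_windows(idx, peaks, w))

  starts <- valid_window_starts(genome, w,
                                exclude = if (exclude_peaks) peaks)
  chrom_of <- rep(names(starts), lengths(starts))
  pos <- unlist(starts, use.names = FALSE)
  if (length(pos) == 0L) stop("no valid window placement exists")
  n <- nrow(peaks)
  draw <- with_seed(seed, sample.int(length(pos), n * R, replace = TRUE))
  wins <- data.frame(chrom = chrom_of[draw], start = pos[draw],
                     end = pos[draw] + w)
  per_win <- count_pairs_in_windows(idx, wins, w)
  repl <- as.integer(rowsum(per_win, rep(seq_len(R), each = n)))
  p <- (1 + sum(repl >= observed)) / (1 + R)
  list(observed = observed, replicate_counts = repl,
       empirical_p = p, R = as.integer(R), seed = as.integer(seed))
}

#' Chi-squared contrast of pair prevalence between two peak classes
#'
#' Builds the 2x2 table (loci with >= 1 pair, loci without) x (class A,
#' class B) and applies Pearson's chi-squared test without continuity
#' correction (df = 1, two-sided).
#'
#' @param with_a,n_a Loci with a pair, and total loci, in class A.
#' @param with_b,n_b Same for class B.
#' @return List with `statistic`, `p_value`, `table`.
#' @export
chisq_class_compare <- function(with_a, n_a, with_b, n_b) {
  tab <- rbind(A = c(with_a, n_a - with_a),
               B = c(with_b, n_b - with_b))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate input: zero margin in 2x2 contrast table")
  }
  # asymptotic form used deliberately; small-count approximation warnings
  # are expected at sparse cells and not informative here
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       table = tab)
}

#' Per-spacer enrichment of a class against a background
#'
#' For each spacer `x`, contrasts (count at `x`, count at all other
#' spacers) in the class against the same split in a pooled random-window
#' background (2x2 chi-squared, uncorrected). The fold change is the ratio
#' of pseudocounted proportions.
#'
#' @param class_counts Integer vector of pair counts over spacers 0..max.
#' @param background_counts Same-length background counts.
#' @param pseudocount Added to each cell of the proportions (default 0.5).
#' @return Data frame with `spacer`, `fold`, `statistic`, `p_value`;
#'   degenerate margins give `p_value = 1` with a warning.
#' @export
spacer_enrichment <- function(class_counts, background_counts,
                              pseudocount = 0.5) {
  stopifnot(length(class_counts) == length(background_counts))
  k <- length(class_counts)
  ctot <- sum(class_counts)
  btot <- sum(background_counts)
  out <- data.frame(spacer = seq_len(k) - 1L, fold = NA_real_,
                    statistic = NA_real_, p_value = NA_real_)
  for (i in seq_len(k)) {
    cx <- class_counts[i]
    bx <- background_counts[i]
    pc <- (cx + pseudocount) / (ctot + pseudocount * k)
    pb <- (bx + pseudocount) / (btot + pseudocount * k)
    out$fold[i] <- pc / pb
    tab <- rbind(c(cx, ctot - cx), c(bx, btot - bx))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("degenerate margins at spacer ", i - 1L, "; p set to 1")
      out$statistic[i] <- 0
      out$p_value[i] <- 1
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      out$statistic[i] <- unname(ht$statistic)
      out$p_value[i] <- unname(ht$p.value)
    }
  }
  out
}
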