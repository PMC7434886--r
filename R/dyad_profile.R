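# Motif-anchored dyad-frequency profiling.
#
# WGATAR (W = A/T, R = A/G) is the GATA-family consensus. Profiles count
# fragment midpoints (dyads) at offsets relative to the anchoring motif
# center, are normalized against a sonicated control, and are summarized as
# a log2 heatmap over +/- 75 bp.

#' Scan a sequence for WGATAR motif hits on both strands
#'
#' A minus-strand hit at `[s, s+6)` means the reverse complement of the
#' plus-strand 6-mer matches WGATAR; equivalently the plus strand shows
#' YTATCW there. Hits containing N never match. Hits are sorted by start,
#' `+` before `-` at equal starts.
#'
#' @param seq Character DNA sequence over A, C, G, T, N.
#' @return Data frame with `start` (0-based, local to `seq`), `end`
#'   (`start + 6`), `strand`, and `matched` (the 6-mer read 5'->3' on its
#'   own strand).
#' @export
wgatar_hits <- function(seq) {
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), matched = character())
  if (nchar(seq) < 6L) return(empty)
  subj <- Biostrings::DNAString(seq)
  plus <- Biostrings::matchPattern("WGATAR", subj, fixed = FALSE)
  minus <- Biostrings::matchPattern("YTATCW", subj, fixed = FALSE)
  ps <- Biostrings::start(plus) - 1L
  ms <- Biostrings::start(minus) - 1L
  pm <- as.character(plus)
  mm <- reverse_complement(as.character(minus))
  df <- data.frame(
    start = c(ps, ms),
    end = c(ps, ms) + 6L,
    strand = c(rep("+", length(ps)), rep("-", length(ms))),
    matched = c(pm, if (length(mm)) mm else character())
  )
  df <- df[!grepl("N", df$matched, fixed = TRUE), , drop = FALSE]
  df <- df[order(df$start, df$strand != "+"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Scan a genomic interval for WGATAR hits
#'
#' @param genome A `"genome"` object.
#' @param chrom Chromosome name.
#' @param start,end Interval in 0-based half-open genomic coordinates.
#' @return As [wgatar_hits()] but with genomic `start`/`end` and a `chrom`
#'   column. An interval shorter than 6 bp yields an empty frame.
#' @export
scan_wgatar <- function(genome, chrom, start, end) {
  if (end - start < 6L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      matched = character()))
  }
  hits <- wgatar_hits(genome_subseq(genome, chrom, start, end))
  data.frame(chrom = rep(chrom, nrow(hits)),
             start = hits$start + start,
             end = hits$end + start,
             strand = hits$strand,
             matched = hits$matched)
}

#' Select the motif hit closest to the peak summit
#'
#' The anchor is the WGATAR hit whose center (`start + 3`) minimizes the
#' distance to the summit (the strongest ChIP-seq signal position); ties go
#' to the smaller start.
#'
#' @param hits Data frame from [scan_wgatar()], restricted to the peak
#'   window.
#' @param summit Genomic summit coordinate.
#' @return A one-row data frame (the chosen hit), or `NULL` if no hits.
#' @export
closest_motif <- function(hits, summit) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  center <- hits$start + 3L
  d <- abs(center - summit)
  i <- order(d, hits$start)[1L]
  hits[i, , drop = FALSE]
}

#' Accumulate fragment midpoints into a motif-anchored dyad profile
#'
#' Each midpoint `m` with `|m - anchor_center| <= K` increments the count at
#' offset `m - anchor_center`. When `orient_by_motif_strand` is `TRUE` and
#' the anchor lies on the minus strand, offsets are negated before binning
#' so the motif's 5'->3' axis points in the same direction at every locus.
#'
#' @param midpoints Integer vector of midpoint genomic coordinates.
#' @param anchor_center Genomic coordinate of the anchoring motif center.
#' @param anchor_strand `"+"` or `"-"`.
#' @param K Half-width of the offset grid in bp (default 150).
#' @param orient_by_motif_strand Flip offsets at minus-strand anchors
#'   (default `TRUE`).
#' @return A `dyad_profile`: list with `offsets` (-K..K), `counts`
#'   (integer, same length) and `n_loci` (1).
#' @export
accumulate_profile <- function(midpoints, anchor_center,
                               anchor_strand = "+", K = 150L,
                               orient_by_motif_strand = TRUE) {
  stopifnot(K >= 1L)
  off <- as.integer(midpoints) - as.integer(anchor_center)
  if (orient_by_motif_strand && identical(anchor_strand, "-")) off <- -off
  off <- off[abs(off) <= K]
  counts <- tabulate(off + K + 1L, nbins = 2L * K + 1L)
  structure(list(offsets = seq(-K, K), counts = as.integer(counts),
                 n_loci = 1L),
            class = "dyad_profile")
}

#' Sum dyad profiles over loci
#'
#' @param profiles List of `dyad_profile` objects on the same offset grid.
#' @return A pooled `dyad_profile` with `n_loci` equal to the number summed.
#' @export
pool_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  off <- profiles[[1L]]$offsets
  counts <- Reduce(`+`, lapply(profiles, function(p) {
    stopifnot(identical(p$offsets, off))
    p$counts
  }))
  structure(list(offsets = off, counts = as.integer(counts),
                 n_loci = sum(vapply(profiles, `[[`, 0L, "n_loci"))),
            class = "dyad_profile")
}

#' Normalize a dyad profile against a sonicated control
#'
#' With pseudocount eps, `ratio_i = ((s_i + eps) / sum(s + eps)) /
#' ((c_i + eps) / sum(c + eps))`. The ratio is invariant under uniform
#' rescaling of either profile's sequencing depth.
#'
#' @param signal,control `dyad_profile` objects on the same offset grid.
#' @param pseudocount Added to every bin before forming proportions
#'   (default 0.5); avoids division by zero at sparse offsets.
#' @return List with `offsets`, `ratio`, `pseudocount`, `signal_total`,
#'   `control_total`.
#' @export
normalize_profile <- function(signal, control, pseudocount = 0.5) {
  stopifnot(identical(signal$offsets, control$offsets))
  s <- signal$counts
  ctl <- control$counts
  if (all(s == 0) && all(ctl == 0)) {
    stop("degenerate input: signal and control are both all-zero")
  }
  ps <- (s + pseudocount) / sum(s + pseudocount)
  pc <- (ctl + pseudocount) / sum(ctl + pseudocount)
  list(offsets = signal$offsets, ratio = ps / pc,
       pseudocount = pseudocount,
       signal_total = sum(s), control_total = sum(ctl))
}

#' Smooth a profile with a discrete Gaussian kernel
#'
#' The kernel is truncated at 3 sigma and renormalized per source position
#' at the boundaries, so total mass is conserved. `sigma_bp = 0` returns the
#' input unchanged.
#'
#' @param counts Numeric vector (e.g. a profile's `counts` or `ratio`).
#' @param sigma_bp Gaussian standard deviation in bp; must be `>= 0`.
#' @return Numeric vector of the same length.
#' @export
smooth_profile <- function(counts, sigma_bp = 15) {
  if (sigma_bp < 0) stop("sigma_bp must be >= 0")
  if (sigma_bp == 0) return(counts)
  r <- max(1L, as.integer(ceiling(3 * sigma_bp)))
  k <- stats::dnorm(seq(-r, r), sd = sigma_bp)
  k <- k / sum(k)
  n <- length(counts)
  out <- numeric(n)
  # per-source renormalization: each position i spreads mass over its
  # in-range kernel support only
  supp <- vapply(seq_len(n), function(i) {
    d <- seq(max(1L, i - r), min(n, i + r)) - i
    sum(k[d + r + 1L])
  }, 0)
  x <- counts / supp
  for (d in seq(-r, r)) {
    src <- seq_len(n)[seq_len(n) + d >= 1L & seq_len(n) + d <= n]
    out[src + d] <- out[src + d] + x[src] * k[d + r + 1L]
  }
  out
}

#' Build a log2 motif-positioning heatmap
#'
#' Rows are (class, condition) groups; columns are offsets within +/- 75 bp
#' of the anchoring motif. Each value is the log2 of the control-normalized
#' dyad-frequency ratio at that offset.
#'
#' @param groups Named list; each element a list with `signal` and `control`
#'   `dyad_profile` objects covering at least +/- `half_width`.
#' @param half_width Column half-span in bp (default 75).
#' @param pseudocount Passed to [normalize_profile()].
#' @return Numeric matrix, rownames the group names, colnames the offsets
#'   (`2 * half_width + 1` columns).
#' @export
build_heatmap <- function(groups, half_width = 75L, pseudocount = 0.5) {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)))
  cols <- seq(-half_width, half_width)
  mat <- matrix(NA_real_, nrow = length(groups), ncol = length(cols),
                dimnames = list(names(groups), as.character(cols)))
  for (g in names(groups)) {
    sig <- restrict_profile(groups[[g]]$signal, half_width)
    ctl <- restrict_profile(groups[[g]]$control, half_width)
    norm <- normalize_profile(sig, ctl, pseudocount)
    mat[g, ] <- log2(norm$ratio)
  }
  mat
}

#' Restrict a dyad profile to a narrower offset window
#'
#' @param profile A `dyad_profile`.
#' @param half_width New half-width; must not exceed the profile's.
#' @return A `dyad_profile` over `-half_width..half_width`.
#' @export
restrict_profile <- function(profile, half_width) {
  keep <- abs(profile$offsets) <= half_width
  if (sum(keep) != 2L * half_width + 1L) {
    stop("profile narrower than requested half-width")
  }
  structure(list(offsets = profile$offsets[keep],
                 counts = profile$counts[keep],
                 n_loci = profile$n_loci),
            class = "dyad_profile")
}

#' Compute pooled per-class dyad profiles from peaks and fragments
#'
#' For each peak the WGATAR hit closest to the summit anchors the locus;
#' midpoints of length-filtered fragments within +/- K of the anchor are
#' accumulated. By default counts are pooled across loci; with
#' `per_locus = TRUE` each locus' counts are first divided by its total so
#' every locus contributes equal weight.
#'
#' @param genome A `"genome"` object.
#' @param peaks Validated peak data frame.
#' @param fragments Fragment data frame (`chrom`, `start`, `end`).
#' @param K Offset half-width (default 150).
#' @param flen_range Mono-nucleosome length band (default `c(120, 200)`).
#' @param orient_by_motif_strand See [accumulate_profile()].
#' @param per_locus Average per-locus-normalized profiles instead of pooling
#'   raw counts (default `FALSE`).
#' @return Named list (by class label) of profiles; for `per_locus = TRUE`
#'   `counts` are reals.
#' @export
class_profiles <- function(genome, peaks, fragments, K = 150L,
                           flen_range = c(120L, 200L),
                           orient_by_motif_strand = TRUE,
                           per_locus = FALSE) {
  fragments <- filter_fragments(fragments, flen_range[1L], flen_range[2L])
  mids <- data.frame(chrom = fragments$chrom,
                     pos = fragment_midpoint(fragments$start, fragments$end))
  mids <- mids[order(mids$chrom, mids$pos), , drop = FALSE]
  by_chrom <- split(mids$pos, mids$chrom)

  out <- list()
  for (cls in sort(unique(peaks$class_label))) {
    sub <- peaks[peaks$class_label == cls, , drop = FALSE]
    counts <- numeric(2L * K + 1L)
    n_loci <- 0L
    for (i in seq_len(nrow(sub))) {
      p <- sub[i, ]
      hits <- scan_wgatar(genome, p$chrom, p$start, p$end)
      anchor <- closest_motif(hits, p$summit)
      if (is.null(anchor)) next
      center <- anchor$start + 3L
      pos <- by_chrom[[p$chrom]]
      if (is.null(pos)) next
      lo <- findInterval(center - K - 0.5, pos)
      hi <- findInterval(center + K + 0.5, pos)
      m <- if (hi > lo) pos[(lo + 1L):hi] else integer()
      prof <- accumulate_profile(m, center, anchor$strand, K,
                                 orient_by_motif_strand)
      if (per_locus) {
        tot <- sum(prof$counts)
        if (tot > 0) counts <- counts + prof$counts / tot
      } else {
        counts <- counts + prof$counts
      }
      n_loci <- n_loci + 1L
    }
    out[[cls]] <- structure(
      list(offsets = seq(-K, K),
           counts = if (per_locus) counts else as.integer(counts),
           n_loci = n_loci),
      class = "dyad_profile")
  }
  out
}
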