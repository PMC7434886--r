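# Shared fixtures and independent oracles for the test suite.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Regex oracle for WGATAR scanning (overlap-aware lookahead), independent
# of the Biostrings-based implementation.
oracle_wgatar <- function(seq) {
  starts <- function(pat) {
    m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer() else as.integer(m) - 1L
  }
  list(plus = starts("(?=[AT]GATA[AG])"),
       minus = starts("(?=[CT]TATC[AT])"))
}

# Brute-force tandem-pair oracle: checks every (start, spacer) combination
# by direct substring comparison on the plus strand.
oracle_tandem_counts <- function(seq, max_spacer = 10L) {
  n <- nchar(seq)
  counts <- list(GG = integer(max_spacer + 1L),
                 GA = integer(max_spacer + 1L))
  for (x in 0:max_spacer) {
    span <- 6L + x
    if (n < span) next
    i <- seq_len(n - span + 1L)
    t1 <- substring(seq, i, i + 2L)
    t2 <- substring(seq, i + 3L + x, i + 5L + x)
    counts$GG[x + 1L] <- sum(t1 == "GAT" & t2 == "GAT") +
      sum(t1 == "ATC" & t2 == "ATC")
    counts$GA[x + 1L] <- sum(t1 == "GAT" & t2 == "ATC")
  }
  counts
}

tandem_counts_from_pairs <- function(pairs, max_spacer = 10L) {
  cnt <- function(o) {
    sub <- pairs[pairs$orientation == o, , drop = FALSE]
    as.integer(table(factor(sub$spacer, levels = 0:max_spacer)))
  }
  list(GG = cnt("GG"), GA = cnt("GA"))
}

# One-peak genome fixture: a window sequence planted in a G background
# (G padding cannot complete a GAT/ATC or WGATAR across a junction).
single_peak_fixture <- function(window_seq, class_label = "G1",
                                window = 200L) {
  pad_left <- (window - nchar(window_seq)) %/% 2L
  win <- paste0(strrep("G", pad_left), window_seq,
                strrep("G", window - pad_left - nchar(window_seq)))
  genome <- as_genome(c(chr1 = paste0(strrep("G", 100), win,
                                      strrep("G", 100))))
  peaks <- data.frame(chrom = "chr1", start = 100L, end = 100L + window,
                      id = "p1", score = 0L, strand = ".",
                      summit = 100L + window %/% 2L,
                      class_label = class_label)
  list(genome = genome, peaks = validate_peaks(peaks, window))
}
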