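# Readers/writers and interval plumbing.
#
# Coordinate convention, used everywhere in this package: 0-based, half-open
# [start, end), i.e. native BED. Any 1-based coordinate is presentation only
# and never stored.

#' Read a multi-record FASTA genome
#'
#' Sequences are uppercased and restricted to the alphabet A, C, G, T, N.
#' Record names are the first whitespace-delimited token of each header and
#' must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of chromosome sequences with class
#'   `"genome"`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("FASTA file has no records: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record name: ", nm[duplicated(nm)][1L])
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record: ", nm[nchar(seqs) == 0L][1L])
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}: ", nm[bad][1L])
  }
  names(seqs) <- nm
  structure(seqs, class = "genome")
}

#' Construct a genome object from in-memory sequences
#'
#' @param seqs Named character vector of chromosome sequences.
#' @return A `"genome"` object.
#' @export
as_genome <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nchar(seqs) > 0L))
  if (anyDuplicated(names(seqs))) stop("duplicate chromosome name")
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  structure(toupper(seqs), class = "genome")
}

#' Write a genome object to FASTA
#'
#' @param genome A `"genome"` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome A `"genome"` object.
#' @return Named integer vector of sequence lengths.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(nchar(unclass(genome)), names(genome))
}

#' Extract a subsequence in 0-based half-open coordinates
#'
#' @param genome A `"genome"` object.
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `0 <= start < end <= length`.
#' @return The `end - start` character subsequence.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- nchar(genome[[chrom]])
  if (!(start >= 0 && start < end && end <= len)) {
    stop("invalid range [", start, ",", end, ") on ", chrom,
         " of length ", len)
  }
  substr(unclass(genome)[[chrom]], start + 1L, end)
}

#' Read a BED3/BED6 file of genomic intervals
#'
#' Validates the BED convention: 0-based half-open, `end > start`,
#' `start >= 0`, integer coordinates. A sixth column, when present, is
#' parsed as the strand and must be one of `+`, `-`, `.`.
#'
#' @param path Path to a tab-separated BED file.
#' @return A data frame with columns `chrom`, `start`, `end`, `strand`
#'   (strand `"."` when absent from the file).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop("BED line with fewer than 3 columns at line ",
         which(ncol < 3L)[1L])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- vapply(fields, `[[`, "", 2L)
  e <- vapply(fields, `[[`, "", 3L)
  if (any(!grepl("^-?[0-9]+$", c(s, e)))) {
    stop("non-integer coordinate in BED file: ", path)
  }
  start <- as.integer(s)
  end <- as.integer(e)
  if (any(start < 0L)) stop("negative start in BED file: ", path)
  if (any(end <= start)) {
    stop("end <= start at BED line ", which(end <= start)[1L])
  }
  strand <- ifelse(ncol >= 6L,
                   vapply(fields, function(f) f[[6L]], ""),
                   ".")
  if (any(!strand %in% c("+", "-", "."))) {
    stop("invalid strand field in BED file: ", path)
  }
  data.frame(chrom = chrom, start = start, end = end, strand = strand)
}

#' Write intervals as BED
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally
#'   `strand` columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if ("strand" %in% names(intervals)) {
    out <- data.frame(intervals$chrom, intervals$start, intervals$end,
                      name = ".", score = 0L, strand = intervals$strand)
  } else {
    out <- data.frame(intervals$chrom, intervals$start, intervals$end)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Midpoint of a mapped fragment, interpreted as the nucleosome dyad
#'
#' Each sequenced mono-nucleosome fragment protects ~147 bp and its midpoint
#' estimates the dyad. For even lengths the tie is broken to the
#' left-of-center base so the result is deterministic:
#' `start + floor((length - 1) / 2)`.
#'
#' @param start,end Fragment coordinates (0-based half-open); vectorized.
#' @return Integer genomic coordinate(s) of the midpoint, always within
#'   `[start, end)`.
#' @export
fragment_midpoint <- function(start, end) {
  stopifnot(all(end > start), all(start >= 0))
  as.integer(start + (end - start - 1L) %/% 2L)
}

#' Filter fragments to a mono-nucleosome length band
#'
#' Mono-nucleosomal fragments were size-selected experimentally; the numeric
#' band is a documented default (120-200 bp) applied before any profiling.
#'
#' @param fragments Data frame with `start`, `end`.
#' @param min_len,max_len Inclusive length bounds in bp.
#' @return The filtered data frame.
#' @export
filter_fragments <- function(fragments, min_len = 120L, max_len = 200L) {
  len <- fragments$end - fragments$start
  fragments[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Read a peak table (BED6+2)
#'
#' Columns: chrom, start, end, id, score, strand, summit, class_label.
#' The summit (an absolute genomic coordinate, typically the position of the
#' strongest ChIP-seq signal) must fall inside the interval, the class label
#' must be one of G1/G2/G3, and every interval must have the configured
#' analysis window length.
#'
#' @param path Path to the tab-separated peak file (with header).
#' @param window Required interval length in bp (default 200).
#' @return Data frame of peaks.
#' @export
read_peaks <- function(path, window = 200L) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_peaks(df, window = window)
}

#' Validate a peak data frame
#'
#' @param peaks Data frame with columns `chrom`, `start`, `end`, `id`,
#'   `summit`, `class_label` (plus optional `score`, `strand`).
#' @param window Required interval length in bp.
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_peaks <- function(peaks, window = 200L) {
  need <- c("chrom", "start", "end", "id", "summit", "class_label")
  if (!all(need %in% names(peaks))) {
    stop("peak table missing columns: ",
         paste(setdiff(need, names(peaks)), collapse = ", "))
  }
  if (any(peaks$end - peaks$start != window)) {
    stop("peak interval length differs from the analysis window (",
         window, " bp)")
  }
  inside <- peaks$summit >= peaks$start & peaks$summit < peaks$end
  if (any(!inside)) stop("peak summit outside its interval")
  if (any(!peaks$class_label %in% c("G1", "G2", "G3"))) {
    stop("class_label must be one of G1, G2, G3")
  }
  peaks
}

#' Write a result table as TSV
#'
#' Writes a header line followed by rows; double columns are rendered with
#' six significant digits.
#'
#' @param rows Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV result table
#'
#' @param path Path written by [write_table()].
#' @return Data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
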