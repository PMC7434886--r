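# Nucleosome rotational geometry.
#
# Positions on nucleosomal DNA are expressed as superhelical location
# (SHL): helical turns from the dyad base pair (SHL0). With the convention
# used throughout this package, half-integer SHLs present the major groove
# to solvent and integer SHLs press it against the histone octamer; the
# boundary between the two regimes is a rotational phase of 0.25 turns.

#' Construct a nucleosome coordinate frame
#'
#' @param dyad_index 0-based index of the dyad base pair within the
#'   construct (default 72, the center of a 145-bp template).
#' @param wrap_length Wrapped DNA length in bp (default 145).
#' @param period Helical period in bp per turn (default 10.4; nucleosomal
#'   twist varies, so this is configurable).
#' @return A `nuc_frame` list.
#' @export
nuc_frame <- function(dyad_index = 72L, wrap_length = 145L, period = 10.4) {
  stopifnot(period > 0, dyad_index >= 0L, dyad_index < wrap_length)
  structure(list(dyad_index = as.integer(dyad_index),
                 wrap_length = as.integer(wrap_length),
                 period = period),
            class = "nuc_frame")
}

#' Superhelical location of a base-pair position
#'
#' @param position 0-based position(s) within the construct.
#' @param frame A [nuc_frame()].
#' @return Signed real SHL: `(position - dyad_index) / period`.
#' @export
shl_of <- function(position, frame) {
  if (any(position < 0L | position >= frame$wrap_length)) {
    stop("position outside the construct [0, ", frame$wrap_length, ")")
  }
  (position - frame$dyad_index) / frame$period
}

#' Groove-face accessibility call at a superhelical location
#'
#' The rotational phase is the fractional part of `|shl|`; positions with
#' `|phase - 0.5| < 0.25` (i.e. near half-integer SHLs) present the major
#' groove to solvent, others to the histone surface. The exact boundary
#' `|phase - 0.5| == 0.25` is assigned to the histone face.
#'
#' @param shl Signed real superhelical location(s).
#' @return Data frame with `shl`, `phase` (in `[0, 1)`) and `face`
#'   (`"solvent_major"` or `"histone_major"`).
#' @export
groove_face <- function(shl) {
  stopifnot(all(is.finite(shl)))
  phase <- abs(shl) %% 1
  face <- ifelse(abs(phase - 0.5) < 0.25, "solvent_major", "histone_major")
  data.frame(shl = shl, phase = phase, face = face)
}

#' Nearest half-integer SHL label for a position
#'
#' @param position 0-based position(s) within the construct.
#' @param frame A [nuc_frame()].
#' @return SHL rounded to the nearest multiple of 0.5.
#' @export
shl_label <- function(position, frame) {
  round(shl_of(position, frame) * 2) / 2
}

#' Classify the nucleosomal geometry of a tandem GAT pair
#'
#' The anchor of each GAT is its center base (`start + 1`). A pair is
#' `dual_exposed_consecutive` when both centers are solvent-exposed major
#' grooves and their SHL separation is within `[0.7, 1.3]` turns
#' (consecutive major grooves, as for a 6-bp spacer: centers 9 bp apart,
#' about 0.87 turns). `one_buried`/`both_buried` count histone-facing
#' centers; anything else (e.g. both exposed but not consecutive) is
#' `other`.
#'
#' @param first_start 0-based construct position of the first GAT.
#' @param spacer Spacer length in bp between the two trinucleotides.
#' @param frame A [nuc_frame()].
#' @return List with `category`, `shl` (both centers), `faces`,
#'   `delta_shl`.
#' @export
classify_tandem_geometry <- function(first_start, spacer, frame) {
  c1 <- first_start + 1L
  c2 <- first_start + 4L + spacer
  if (c1 < 0L || c2 >= frame$wrap_length) {
    stop("motif outside the wrapped region")
  }
  shl <- shl_of(c(c1, c2), frame)
  gf <- groove_face(shl)
  d <- abs(shl[2L] - shl[1L])
  n_buried <- sum(gf$face == "histone_major")
  category <- if (n_buried == 2L) {
    "both_buried"
  } else if (n_buried == 1L) {
    "one_buried"
  } else if (d >= 0.7 && d <= 1.3) {
    "dual_exposed_consecutive"
  } else {
    "other"
  }
  list(category = category, shl = shl, faces = gf$face, delta_shl = d)
}

# --- construct design -------------------------------------------------------

new_construct <- function(name, sequence, template) {
  stopifnot(nchar(sequence) == nchar(template))
  pos <- which(strsplit(sequence, "")[[1L]] != strsplit(template, "")[[1L]])
  edits <- if (length(pos) == 0L) {
    data.frame(position = integer(), from_base = character(),
               to_base = character())
  } else {
    data.frame(position = pos - 1L,
               from_base = substring(template, pos, pos),
               to_base = substring(sequence, pos, pos))
  }
  list(name = name, sequence = sequence, edits = edits)
}

replace_at <- function(seq, start0, replacement) {
  stopifnot(start0 >= 0L, start0 + nchar(replacement) <= nchar(seq))
  paste0(substr(seq, 1L, start0),
         replacement,
         substr(seq, start0 + nchar(replacement) + 1L, nchar(seq)))
}

#' Insert a GATA-binding motif at a target superhelical location
#'
#' Overwrites template bases with the 11-bp motif `AGATANCATCT` (N kept as
#' the template base at that position) so that the center of the motif's
#' first GAT lands on the base pair nearest `target_shl`. Length is
#' preserved and all real changes are recorded as edits.
#'
#' @param template Template DNA sequence (e.g. a 145-bp Widom-601-style
#'   positioning sequence).
#' @param frame A [nuc_frame()].
#' @param target_shl Target superhelical location for the first GAT center.
#' @param name Construct name.
#' @param motif Inserted motif (default `"AGATANCATCT"`; its first GAT
#'   center is at motif index 2).
#' @return A construct: list with `name`, `sequence`, `edits` (data frame
#'   of position/from/to).
#' @export
design_insertion <- function(template, frame, target_shl, name,
                             motif = "AGATANCATCT") {
  center <- frame$dyad_index + as.integer(round(target_shl * frame$period))
  start <- center - 2L
  if (start < 0L || start + nchar(motif) > nchar(template)) {
    stop("insertion footprint out of template bounds")
  }
  ins <- strsplit(motif, "")[[1L]]
  tmpl <- strsplit(substr(template, start + 1L, start + nchar(motif)),
                   "")[[1L]]
  ins[ins == "N"] <- tmpl[ins == "N"]
  seq <- replace_at(template, start, paste(ins, collapse = ""))
  new_construct(name, seq, template)
}

#' Design a rotational series of motif insertions
#'
#' Five constructs (suffixes a-e by default) stepping the target SHL in
#' increments of `step_shl` around a central location, sampling rotational
#' settings across roughly one helical turn.
#'
#' @param template Template DNA sequence.
#' @param frame A [nuc_frame()].
#' @param center_shl Central superhelical location (e.g. 2 or 5).
#' @param n Number of constructs (default 5).
#' @param step_shl SHL increment between consecutive constructs
#'   (default 0.2, about 2 bp).
#' @param prefix Name prefix (default `"SHL<center>"`).
#' @return Named list of constructs.
#' @export
design_insertion_series <- function(template, frame, center_shl, n = 5L,
                                    step_shl = 0.2,
                                    prefix = paste0("SHL", center_shl)) {
  targets <- center_shl + (seq_len(n) - 1L) * step_shl
  names <- paste0(prefix, letters[seq_len(n)])
  out <- Map(function(t, nm) design_insertion(template, frame, t, nm),
             targets, names)
  names(out) <- names
  out
}

#' Knock out a GAT/ATC trinucleotide with a minimal edit
#'
#' Substitutes the middle base (preference order C > G > T > A) so that the
#' trinucleotide is no longer GAT or ATC on either strand and no new GAT or
#' ATC is created within 4 bp of the edit.
#'
#' @param sequence DNA sequence.
#' @param gat_start 0-based start of a GAT (or ATC) trinucleotide.
#' @param name Construct name (default derived from the position).
#' @return A construct list (`name`, `sequence`, `edits`).
#' @export
knockout_gat <- function(sequence, gat_start,
                         name = paste0("dGAT_", gat_start)) {
  tri <- substr(sequence, gat_start + 1L, gat_start + 3L)
  if (!tri %in% c("GAT", "ATC")) {
    stop("no GAT/ATC trinucleotide at position ", gat_start)
  }
  mid <- substr(sequence, gat_start + 2L, gat_start + 2L)
  for (b in setdiff(c("C", "G", "T", "A"), mid)) {
    cand <- replace_at(sequence, gat_start + 1L, b)
    lo <- max(0L, gat_start - 4L)
    hi <- min(nchar(cand), gat_start + 3L + 4L)
    win <- substr(cand, lo + 1L, hi)
    if (!grepl("GAT", win, fixed = TRUE) &&
        !grepl("ATC", win, fixed = TRUE)) {
      return(new_construct(name, cand, sequence))
    }
  }
  stop("no valid substitution disrupts the site without creating a new one")
}

#' GAT occurrences on either strand of a sequence
#'
#' A plus-strand GAT appears as `GAT`; a minus-strand GAT appears as `ATC`
#' on the plus strand.
#'
#' @param seq DNA sequence.
#' @return Data frame with `start` (0-based) and `strand`.
#' @export
scan_gat <- function(seq) {
  gat <- gat_triplet_starts(seq, "GAT")
  atc <- gat_triplet_starts(seq, "ATC")
  df <- data.frame(start = c(gat, atc),
                   strand = c(rep("+", length(gat)),
                              rep("-", length(atc))))
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# --- synthetic 601-style template ------------------------------------------

# Plant a guarded trinucleotide centered at `center` (0-based): "GGATT"
# for GAT, "GCATC" for ATC. The guard bases are chosen so that no triplet
# spanning a junction with arbitrary flanking sequence can read GAT or ATC
# on either strand (e.g. a left flank ending in "A","T" cannot complete
# ATC against the first guard base).
plant_guarded_triplet <- function(seq, center, triplet = c("GAT", "ATC")) {
  triplet <- match.arg(triplet)
  if (triplet == "GAT") {
    replace_at(seq, center - 2L, "GGATT")
  } else {
    replace_at(seq, center - 3L, "GCATC")
  }
}

#' Synthetic 145-bp Widom-601-style template
#'
#' A deterministic stand-in for a strongly positioning 145-bp nucleosome
#' template: a seeded random sequence scrubbed of every GAT/ATC
#' trinucleotide and of WGATAR motifs, then given exactly three intrinsic
#' GAT elements at the positions the geometry analysis cares about (in the
#' default frame: a plus-strand GAT near SHL2, a minus-strand GAT on the
#' left arm, and a plus-strand GAT whose center sits in the SHL6.5 major
#' groove). This synthetic template is NOT the published Widom 601
#' sequence; it reproduces its GAT content and layout, not its base
#' composition or positioning strength.
#'
#' @param seed Integer seed (default 601).
#' @param frame A [nuc_frame()]; the intrinsic GAT positions are placed
#'   relative to this frame.
#' @return A 145-bp character sequence with exactly three GAT/ATC sites.
#' @export
make_widom601_synthetic <- function(seed = 601L, frame = nuc_frame()) {
  n <- frame$wrap_length
  seq <- with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c(0.23, 0.27, 0.27, 0.23)),
    collapse = ""))
  # scrub every GAT/ATC (both strands) and every WGATAR by middle-base edits
  for (iter in 1:50) {
    sg <- scan_gat(seq)
    wh <- wgatar_hits(seq)
    if (nrow(sg) == 0L && nrow(wh) == 0L) break
    if (nrow(sg) > 0L) {
      seq <- replace_at(seq, sg$start[1L] + 1L, "C")
    } else {
      seq <- replace_at(seq, wh$start[1L] + 3L, "C")
    }
  }
  stopifnot(nrow(scan_gat(seq)) == 0L, nrow(wgatar_hits(seq)) == 0L)
  # three intrinsic sites: left-arm minus-strand GAT, SHL2-region GAT, and
  # a GAT centered in the SHL6.5 major groove (6-bp spacer downstream of a
  # SHL5.5 insertion site)
  centers <- frame$dyad_index + c(
    -as.integer(round(3.1 * frame$period)),
    as.integer(round(2.2 * frame$period)),
    as.integer(round(5.5 * frame$period)) + 9L)
  seq <- plant_guarded_triplet(seq, centers[1L], "ATC")
  seq <- plant_guarded_triplet(seq, centers[2L], "GAT")
  seq <- plant_guarded_triplet(seq, centers[3L], "GAT")
  stopifnot(nrow(scan_gat(seq)) == 3L)
  seq
}

#' Synthetic SHL5e-style construct
#'
#' Reproduces the layout described for the SHL5e nucleosome: on top of the
#' synthetic 601-style template (whose intrinsic downstream GAT center sits
#' in the SHL6.5 major groove), two further plus-strand GATs are planted
#' with centers at the base pairs nearest SHL5 and SHL5.5. The SHL5.5 and
#' SHL6.5 GATs end up separated by a 6-bp spacer — consecutive
#' solvent-exposed major grooves — while the SHL5 GAT faces the histone
#' surface.
#'
#' @param template Template sequence (default
#'   [make_widom601_synthetic()]).
#' @param frame A [nuc_frame()].
#' @return A construct list (`name`, `sequence`, `edits`).
#' @export
design_shl5e <- function(template = make_widom601_synthetic(frame = frame),
                         frame = nuc_frame()) {
  c55 <- frame$dyad_index + as.integer(round(5.5 * frame$period))
  c5 <- frame$dyad_index + as.integer(round(5.0 * frame$period))
  seq <- plant_guarded_triplet(template, c5, "GAT")
  seq <- plant_guarded_triplet(seq, c55, "GAT")
  new_construct("SHL5e", seq, template)
}
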