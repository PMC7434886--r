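# Seeded generator of synthetic genomes, class-labeled peak sets and
# fragment files with the statistical structure the analysis assumes:
#
#   G1  productively remodeled loci: a convergent GAT-{3,4}bp-ATC tandem at
#       the summit; dyads symmetric at +/-21 bp (about two helical turns,
#       SHL2) before factor expression, pushed beyond 100 bp after.
#   G2  pre-accessible loci: a single WGATAR in a nucleosome-depleted
#       region; dyads excluded within +/-80 bp of the motif.
#   G3  non-productive loci: a same-strand GAT-6bp-GAT tandem; dyads
#       unpositioned before, at +/-52 bp (about five helical turns, SHL5)
#       after.
#
# Sonicated controls are uniform over the peak window plus a margin.

# Planted plan sequences. Each contains a WGATAR anchor (center at plan
# index 3) and the class tandem; spacer bases are G/C so no stray GAT/ATC
# arises inside the plan.
plan_sequence <- function(class_label, spacer = NA) {
  switch(class_label,
         G1 = if (spacer == 3) "AGATAGCATCT" else "AGATAGGCATCT",
         G2 = "TGATAA",
         G3 = "AGATAGCGCGGAT",
         stop("unknown class: ", class_label))
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: 200-bp peak
#' windows; G1 tandem spacers 3 or 4 (equal weight); G3 spacer 6; dyad
#' offsets +/-21 bp (sd 3) for G1 before expression and +/-130 bp (sd 15)
#' after; +/-52 bp (sd 3) for G3 after; G2 dyads excluded within +/-80 bp
#' of the motif; fragment lengths about 147 +/- 10 bp truncated to the
#' mono-nucleosome band.
#'
#' @param seed Integer master seed; the whole simulation is a pure function
#'   of the configuration including this seed.
#' @param genome_length Background genome length in bp.
#' @param base_freq Named iid base probabilities.
#' @param n_peaks Named vector of peak counts per class.
#' @param peak_window Analysis window width in bp.
#' @param scrub Disrupt background WGATAR occurrences by single-base
#'   substitution (default `FALSE`).
#' @param g1_spacers,g1_spacer_weights Spacer choices for the G1 tandem.
#' @param dyad_models Named list of dyad-offset models, one per
#'   `"<class>_<condition>"`. Each is either
#'   `list(type = "mixture", offsets =, sd =, weights =)` (Gaussian mixture
#'   around the motif center, truncated only by rounding),
#'   `list(type = "uniform")` (uniform over the window) or
#'   `list(type = "uniform_excluding", exclude =)` (uniform over the window
#'   minus a central exclusion zone). Defaults encode the class
#'   phenomenology above.
#' @param fragments_per_locus Fragments simulated per locus per condition.
#' @param fragment_length_mean,fragment_length_sd Fragment length model.
#' @param flen_range Mono-nucleosome truncation band.
#' @param control_margin Extra bp on each side of the window for the
#'   sonicated control.
#' @param control_depth Control fragments per locus (default: same as
#'   signal).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1000000L,
                       base_freq = c(A = 0.25, C = 0.25,
                                     G = 0.25, T = 0.25),
                       n_peaks = c(G1 = 100L, G2 = 100L, G3 = 100L),
                       peak_window = 200L,
                       scrub = FALSE,
                       g1_spacers = c(3L, 4L),
                       g1_spacer_weights = c(0.5, 0.5),
                       dyad_models = default_dyad_models(),
                       fragments_per_locus = 200L,
                       fragment_length_mean = 147,
                       fragment_length_sd = 10,
                       flen_range = c(120L, 200L),
                       control_margin = 100L,
                       control_depth = NULL) {
  stopifnot(abs(sum(base_freq) - 1) < 1e-9, all(base_freq >= 0),
            abs(sum(g1_spacer_weights) - 1) < 1e-9,
            genome_length > 0, peak_window > 0)
  need <- sum(n_peaks) * (peak_window + 100L)
  if (genome_length < need) {
    stop("genome too short for the requested peaks (need >= ", need, " bp)")
  }
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 base_freq = base_freq,
                 n_peaks = n_peaks,
                 peak_window = as.integer(peak_window),
                 scrub = scrub,
                 g1_spacers = g1_spacers,
                 g1_spacer_weights = g1_spacer_weights,
                 dyad_models = dyad_models,
                 fragments_per_locus = as.integer(fragments_per_locus),
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 flen_range = flen_range,
                 control_margin = as.integer(control_margin),
                 control_depth = control_depth),
            class = "sim_config")
}

#' Generate the background genome
#'
#' iid draws from the configured base frequencies on a single chromosome
#' `"chrS"`. With `scrub = TRUE` every background WGATAR occurrence (either
#' strand) is disrupted by substituting the T of its GATA core, iterating
#' until no hit remains.
#'
#' @param config A [sim_config()].
#' @return A `"genome"` object.
#' @export
make_genome <- function(config) {
  seq <- with_seed(derive_seed(config$seed, "genome"), paste(
    sample(names(config$base_freq), config$genome_length, replace = TRUE,
           prob = config$base_freq),
    collapse = ""))
  if (config$scrub) {
    repeat {
      hits <- wgatar_hits(seq)
      if (nrow(hits) == 0L) break
      ch <- strsplit(seq, "")[[1L]]
      # base 3 of the plus-strand 6-mer is the T of GATA (plus hits) or the
      # T of TATC (minus hits); C disrupts both without creating new cores
      ch[hits$start + 4L] <- "C"
      seq <- paste(ch, collapse = "")
    }
  }
  as_genome(c(chrS = seq))
}

#' Plant class-labeled peaks with their motif plans
#'
#' Peak windows are placed without overlap (at least 100 bp apart); each
#' receives its class plan sequence centered so the WGATAR anchor center
#' coincides with the summit (the window center). Planted tandem
#' coordinates are recorded in a truth table.
#'
#' @param genome Background `"genome"` from [make_genome()].
#' @param config A [sim_config()].
#' @return List with the edited `genome`, a `peaks` data frame
#'   (BED6+2 schema) and a `truth` data frame (`id`, `class_label`,
#'   `motif_center`, `orientation`, `spacer`, `pair_first_start`).
#' @export
plant_peaks <- function(genome, config) {
  w <- config$peak_window
  gap <- 100L
  L <- config$genome_length
  n_total <- sum(config$n_peaks)
  n_slots <- (L - gap) %/% (w + gap)
  if (n_slots < n_total) stop("infeasible non-overlapping peak placement")
  sd <- derive_seed(config$seed, "peaks")
  slots <- with_seed(sd, sort(sample.int(n_slots, n_total)))
  starts <- gap + (slots - 1L) * (w + gap)
  classes <- rep(names(config$n_peaks), config$n_peaks)
  spacers <- with_seed(derive_seed(config$seed, "spacers"), {
    ifelse(classes == "G1",
           sample(config$g1_spacers, n_total, replace = TRUE,
                  prob = config$g1_spacer_weights),
           ifelse(classes == "G3", 6L, NA_integer_))
  })

  seq <- unclass(genome)[[1L]]
  chrom <- names(genome)[1L]
  peaks <- data.frame(chrom = chrom, start = starts, end = starts + w,
                      id = sprintf("peak_%04d", seq_len(n_total)),
                      score = 0L, strand = ".",
                      summit = starts + w %/% 2L,
                      class_label = classes)
  truth <- data.frame(id = peaks$id, class_label = classes,
                      motif_center = peaks$summit,
                      orientation = ifelse(classes == "G1", "GA",
                                           ifelse(classes == "G3", "GG",
                                                  NA_character_)),
                      spacer = spacers,
                      pair_first_start = NA_integer_)
  for (i in seq_len(n_total)) {
    plan <- plan_sequence(classes[i], spacers[i])
    # WGATAR anchor center is plan index 3; align it with the summit
    plan_start <- peaks$summit[i] - 3L
    seq <- replace_at(seq, plan_start, plan)
    if (classes[i] %in% c("G1", "G3")) {
      truth$pair_first_start[i] <- plan_start + 1L  # first GAT of the plan
    }
  }
  list(genome = as_genome(stats::setNames(seq, chrom)),
       peaks = validate_peaks(peaks, w), truth = truth)
}

#' Default dyad-offset models per class and condition
#'
#' G1 dyads sit symmetrically two helical turns (+/-21 bp, SHL2) from the
#' motif before factor expression and beyond 100 bp (+/-130) after; G2
#' dyads avoid the motif (+/-80 bp exclusion) in both conditions; G3 dyads
#' are unpositioned before and five helical turns out (+/-52 bp, SHL5)
#' after.
#'
#' @return Named list of model specifications (see [sim_config()]).
#' @export
default_dyad_models <- function() {
  list(
    G1_pre = list(type = "mixture", offsets = c(-21, 21), sd = 3,
                  weights = c(0.5, 0.5)),
    G1_post = list(type = "mixture", offsets = c(-130, 130), sd = 15,
                   weights = c(0.5, 0.5)),
    G2_pre = list(type = "uniform_excluding", exclude = 80L),
    G2_post = list(type = "uniform_excluding", exclude = 80L),
    G3_pre = list(type = "uniform"),
    G3_post = list(type = "mixture", offsets = c(-52, 52), sd = 3,
                   weights = c(0.5, 0.5)))
}

dyad_offsets <- function(config, class_label, condition, n) {
  half <- config$peak_window %/% 2L
  model <- config$dyad_models[[paste(class_label, condition, sep = "_")]]
  if (is.null(model)) {
    stop("no dyad model for ", class_label, " / ", condition)
  }
  switch(model$type,
    mixture = {
      mu <- sample(model$offsets, n, replace = TRUE, prob = model$weights)
      if (model$sd > 0) mu <- mu + stats::rnorm(n, 0, model$sd)
      round(mu)
    },
    uniform = sample(seq(-half, half), n, replace = TRUE),
    uniform_excluding = {
      ex <- model$exclude
      sample(c(seq(-half, -ex - 1L), seq(ex + 1L, half)), n,
             replace = TRUE)
    },
    stop("unknown dyad model type: ", model$type))
}

fragment_lengths <- function(n, mean, sd, range) {
  len <- round(stats::rnorm(n, mean, sd))
  bad <- len < range[1L] | len > range[2L]
  for (i in 1:20) {
    if (!any(bad)) break
    len[bad] <- round(stats::rnorm(sum(bad), mean, sd))
    bad <- len < range[1L] | len > range[2L]
  }
  pmin(pmax(len, range[1L]), range[2L])
}

fragments_from_midpoints <- function(mid, len, chrom, chrom_len) {
  start <- mid - (len - 1L) %/% 2L
  start <- pmax(0L, pmin(start, chrom_len - len))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len))
}

#' Simulate nucleosomal fragments for one condition
#'
#' Per locus, `fragments_per_locus` fragments whose midpoint is the motif
#' center plus a draw from the class/condition dyad-offset model, with
#' fragment lengths from the truncated length model.
#'
#' @param peaks Peak data frame from [plant_peaks()].
#' @param truth Truth data frame from [plant_peaks()].
#' @param config A [sim_config()].
#' @param condition `"pre"` or `"post"` (factor expression).
#' @return Fragment data frame (`chrom`, `start`, `end`).
#' @export
simulate_fragments <- function(peaks, truth, config,
                               condition = c("pre", "post")) {
  condition <- match.arg(condition)
  n <- config$fragments_per_locus
  with_seed(derive_seed(config$seed, paste0("fragments_", condition)), {
    parts <- lapply(seq_len(nrow(peaks)), function(i) {
      off <- dyad_offsets(config, peaks$class_label[i], condition, n)
      mid <- truth$motif_center[i] + as.integer(off)
      len <- fragment_lengths(n, config$fragment_length_mean,
                              config$fragment_length_sd,
                              config$flen_range)
      fragments_from_midpoints(mid, len, peaks$chrom[i],
                               config$genome_length)
    })
    do.call(rbind, parts)
  })
}

#' Simulate the sonicated control
#'
#' Midpoints uniform over each peak window extended by the configured
#' margin; same per-locus depth as the signal unless `control_depth` is
#' set.
#'
#' @param peaks Peak data frame.
#' @param config A [sim_config()].
#' @return Fragment data frame (`chrom`, `start`, `end`).
#' @export
simulate_control <- function(peaks, config) {
  depth <- if (is.null(config$control_depth)) {
    config$fragments_per_locus
  } else {
    config$control_depth
  }
  if (depth == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  m <- config$control_margin
  with_seed(derive_seed(config$seed, "control"), {
    parts <- lapply(seq_len(nrow(peaks)), function(i) {
      lo <- peaks$start[i] - m
      hi <- peaks$end[i] - 1L + m
      mid <- sample(seq(lo, hi), depth, replace = TRUE)
      len <- fragment_lengths(depth, config$fragment_length_mean,
                              config$fragment_length_sd,
                              config$flen_range)
      fragments_from_midpoints(mid, len, peaks$chrom[i],
                               config$genome_length)
    })
    do.call(rbind, parts)
  })
}

#' Run the whole simulation, optionally writing files
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `peaks.tsv`, `truth.tsv`, `fragments_pre.bed`, `fragments_post.bed`
#'   and `control.bed`.
#' @return List with `genome`, `peaks`, `truth`, `fragments_pre`,
#'   `fragments_post`, `control`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  planted <- plant_peaks(make_genome(config), config)
  res <- list(genome = planted$genome,
              peaks = planted$peaks,
              truth = planted$truth,
              fragments_pre = simulate_fragments(planted$peaks,
                                                 planted$truth, config,
                                                 "pre"),
              fragments_post = simulate_fragments(planted$peaks,
                                                  planted$truth, config,
                                                  "post"),
              control = simulate_control(planted$peaks, config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(res$genome, file.path(out_dir, "genome.fa"))
    write_table(res$peaks, file.path(out_dir, "peaks.tsv"))
    write_table(res$truth, file.path(out_dir, "truth.tsv"))
    write_bed(res$fragments_pre, file.path(out_dir, "fragments_pre.bed"))
    write_bed(res$fragments_post, file.path(out_dir, "fragments_post.bed"))
    write_bed(res$control, file.path(out_dir, "control.bed"))
  }
  res
}
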