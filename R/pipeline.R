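# Pipeline orchestration: runs simulate -> profile -> spacing -> geometry
# in dependency order, writing result TSVs and a JSON run manifest. Each
# stage draws randomness from a seed derived from the global seed and the
# stage name, so stages are reproducible independently of execution order.

pipeline_params <- function(config, opts) {
  c(list(seed = config$seed,
         genome_length = config$genome_length,
         n_peaks = as.list(config$n_peaks),
         peak_window = config$peak_window,
         scrub = config$scrub,
         fragments_per_locus = config$fragments_per_locus),
    opts)
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Stages: `simulate` (genome, peaks, fragments, control), `profile`
#' (per-class metaplots and the log2 motif-positioning heatmap), `spacing`
#' (tandem-pair table, analytic expectations, Monte Carlo enrichment,
#' class contrasts, per-spacer enrichment) and `geometry` (groove-face
#' classification of the planted tandems in a construct frame, plus the
#' construct design series). All result tables are TSV; a `manifest.json`
#' records parameters, file digests, seeds and status. A stage failure
#' leaves earlier outputs intact and the manifest marked `failed` with the
#' stage name.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param K Metaplot offset half-width in bp (default 150).
#' @param heatmap_half_width Heatmap half-span (default 75).
#' @param pseudocount Normalization pseudocount (default 0.5).
#' @param sigma Gaussian smoothing sd in bp for the smoothed metaplot
#'   column (default 15).
#' @param mc_replicates Monte Carlo replicates (default 200).
#' @return Invisibly, the manifest list. Errors (after writing the failed
#'   manifest) if any stage fails.
#' @export
run_pipeline <- function(config, out_dir, K = 150L,
                         heatmap_half_width = 75L, pseudocount = 0.5,
                         sigma = 15, mc_replicates = 200L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    subcommand = "run-all",
    parameters = pipeline_params(config, list(
      K = K, heatmap_half_width = heatmap_half_width,
      pseudocount = pseudocount, sigma = sigma,
      mc_replicates = mc_replicates)),
    stage_seeds = list(
      genome = derive_seed(config$seed, "genome"),
      peaks = derive_seed(config$seed, "peaks"),
      monte_carlo = derive_seed(config$seed, "monte_carlo")),
    version = as.character(utils::packageVersion("nucpioneer")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    status = "running", failed_stage = NULL)

  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  data <- run_stage("simulate", function() simulate_dataset(config, out_dir))
  run_stage("profile", function() {
    stage_profile(data, out_dir, K, heatmap_half_width, pseudocount, sigma)
  })
  run_stage("spacing", function() {
    stage_spacing(data, out_dir, config, mc_replicates)
  })
  run_stage("geometry", function() stage_geometry(data, out_dir, config))

  manifest$inputs <- as.list(tools::md5sum(
    file.path(out_dir, c("genome.fa", "peaks.tsv", "fragments_pre.bed",
                         "fragments_post.bed", "control.bed"))))
  names(manifest$inputs) <- basename(names(manifest$inputs))
  manifest$status <- "success"
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_manifest()
  invisible(manifest)
}

stage_profile <- function(data, out_dir, K, half_width, pseudocount,
                          sigma) {
  groups <- list()
  rows <- list()
  for (cond in c("pre", "post")) {
    frags <- data[[paste0("fragments_", cond)]]
    sig <- class_profiles(data$genome, data$peaks, frags, K = K)
    ctl <- class_profiles(data$genome, data$peaks, data$control, K = K)
    for (cls in names(sig)) {
      norm <- normalize_profile(sig[[cls]], ctl[[cls]], pseudocount)
      rows[[paste(cls, cond)]] <- data.frame(
        class_label = cls, condition = cond,
        offset = sig[[cls]]$offsets,
        raw = sig[[cls]]$counts,
        control = ctl[[cls]]$counts,
        ratio = norm$ratio,
        ratio_smoothed = smooth_profile(norm$ratio, sigma))
      groups[[paste0(cls, "_", cond)]] <-
        list(signal = sig[[cls]], control = ctl[[cls]])
    }
  }
  write_table(do.call(rbind, rows), file.path(out_dir, "metaplot.tsv"))
  hm <- build_heatmap(groups, half_width, pseudocount)
  hm_df <- data.frame(row = rownames(hm), hm, check.names = FALSE)
  write_table(hm_df, file.path(out_dir, "heatmap.tsv"))
  invisible(hm)
}

stage_spacing <- function(data, out_dir, config, mc_replicates) {
  tab <- spacing_table(data$peaks, data$genome)
  bg_n <- nrow(data$peaks)
  bg_seed <- derive_seed(config$seed, "background_windows")
  bg_wins <- sample_random_windows(data$genome, bg_n, config$peak_window,
                                   exclude = data$peaks, seed = bg_seed)
  bg <- lapply(seq_len(bg_n), function(i) {
    find_tandem_pairs(genome_subseq(data$genome, bg_wins$chrom[i],
                                    bg_wins$start[i], bg_wins$end[i]))
  })
  bg <- do.call(rbind, bg)
  bg_counts <- function(orient) {
    sub <- bg[bg$orientation == orient, , drop = FALSE]
    as.integer(table(factor(sub$spacer, levels = 0:10)))
  }

  rows <- list()
  for (cls in c("G1", "G2", "G3")) {
    for (o in c("GG", "GA")) {
      enr <- spacer_enrichment(tab$counts[cls, o, ], bg_counts(o))
      exp_p <- expected_pair_probability(config$base_freq, o)
      rows[[paste(cls, o)]] <- data.frame(
        class_label = cls, orientation = o, spacer = 0:10,
        pair_count = tab$counts[cls, o, ],
        loci_with_pair = tab$loci_with_pair[cls, o, ],
        expected_per_position = exp_p,
        fold_vs_background = enr$fold, chisq = enr$statistic,
        p_value = enr$p_value)
    }
  }
  write_table(do.call(rbind, rows), file.path(out_dir, "spacing.tsv"))

  contrasts <- list(c("G1", "G2", "GG"), c("G3", "G2", "GG"),
                    c("G1", "G2", "GA"), c("G1", "G3", "GA"))
  crows <- lapply(contrasts, function(ct) {
    # presence/absence of >= 1 pair per locus, recomputed directly (the
    # per-spacer loci_with_pair cells cannot be summed: one locus may
    # contribute at several spacers)
    pres <- loci_with_any_pair(data$peaks, data$genome, ct[3L])
    cc <- chisq_class_compare(pres[[ct[1L]]], tab$n_peaks[[ct[1L]]],
                              pres[[ct[2L]]], tab$n_peaks[[ct[2L]]])
    data.frame(class_a = ct[1L], class_b = ct[2L], orientation = ct[3L],
               with_a = pres[[ct[1L]]], n_a = tab$n_peaks[[ct[1L]]],
               with_b = pres[[ct[2L]]], n_b = tab$n_peaks[[ct[2L]]],
               statistic = cc$statistic, p_value = cc$p_value)
  })
  write_table(do.call(rbind, crows), file.path(out_dir, "contrasts.tsv"))

  mc <- monte_carlo_enrichment(data$peaks, data$genome, "any",
                               R = mc_replicates,
                               seed = derive_seed(config$seed,
                                                  "monte_carlo"))
  write_table(data.frame(observed = mc$observed, R = mc$R,
                         empirical_p = mc$empirical_p,
                         null_mean = mean(mc$replicate_counts),
                         null_max = max(mc$replicate_counts)),
              file.path(out_dir, "enrichment.tsv"))
  invisible(mc)
}

# per-class count of peaks containing >= 1 pair of the given orientation
loci_with_any_pair <- function(peaks, genome, orientation) {
  out <- c(G1 = 0L, G2 = 0L, G3 = 0L)
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    pairs <- find_tandem_pairs(genome_subseq(genome, p$chrom, p$start,
                                             p$end))
    if (any(pairs$orientation == orientation)) {
      out[[p$class_label]] <- out[[p$class_label]] + 1L
    }
  }
  out
}

stage_geometry <- function(data, out_dir, config) {
  frame <- nuc_frame()
  # map each planted tandem into the construct frame with its first GAT
  # center at the bp nearest SHL5.5, then classify
  truth <- data$truth[!is.na(data$truth$spacer), , drop = FALSE]
  anchor <- frame$dyad_index + as.integer(round(5.5 * frame$period)) - 1L
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    cl <- classify_tandem_geometry(anchor, truth$spacer[i], frame)
    data.frame(id = truth$id[i], class_label = truth$class_label[i],
               orientation = truth$orientation[i],
               spacer = truth$spacer[i],
               shl_first = cl$shl[1L], shl_second = cl$shl[2L],
               face_first = cl$faces[1L], face_second = cl$faces[2L],
               delta_shl = cl$delta_shl, category = cl$category)
  })
  write_table(do.call(rbind, rows), file.path(out_dir, "geometry.tsv"))

  template <- make_widom601_synthetic(frame = frame)
  series <- c(design_insertion_series(template, frame, 2),
              design_insertion_series(template, frame, 5),
              list(SHL5e_tandem = design_shl5e(template, frame)))
  fa <- stats::setNames(vapply(series, `[[`, "", "sequence"),
                        names(series))
  write_fasta(as_genome(c(template_synthetic = template, fa)),
              file.path(out_dir, "constructs_synthetic.fa"))
  edits <- do.call(rbind, lapply(series, function(cn) {
    if (nrow(cn$edits) == 0L) return(NULL)
    data.frame(name = cn$name, cn$edits)
  }))
  write_table(edits, file.path(out_dir, "construct_edits.tsv"))
  invisible(series)
}
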