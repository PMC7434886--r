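#!/usr/bin/env Rscript
# Generate the synthetic study dataset: a 1 Mb background genome, 300
# class-labeled 200-bp peak windows (G1/G2/G3, 100 each) with planted
# motif plans, nucleosomal fragments for the pre- and post-expression
# conditions, and a sonicated control. All downstream drivers read the
# files written here.

suppressPackageStartupMessages(library(nucpioneer))

out <- "results/sim"
cfg <- sim_config(seed = 1L)
data <- simulate_dataset(cfg, out_dir = out)

cat("genome:", genome_lengths(data$genome), "bp on",
    length(data$genome), "chromosome\n")
cat("peaks:", nrow(data$peaks), "(",
    paste(names(table(data$peaks$class_label)),
          table(data$peaks$class_label), collapse = ", "), ")\n")
cat("fragments per condition:", nrow(data$fragments_pre), "\n")
cat("planted spacers: G1 ->",
    paste(sort(unique(data$truth$spacer[data$truth$class_label == "G1"])),
          collapse = "/"),
    "; G3 ->",
    unique(data$truth$spacer[data$truth$class_label == "G3"]), "\n")
cat("written to", out, "\n")
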