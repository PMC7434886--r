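#!/usr/bin/env Rscript
# Nucleosome rotational geometry of the planted tandems, and the
# construct-design series: the synthetic 601-style template, SHL2a-e and
# SHL5a-e motif insertions, the SHL5e tandem construct, and its single-GAT
# knockouts.

suppressPackageStartupMessages(library(nucpioneer))

sim <- "results/sim"
truth <- read_table_tsv(file.path(sim, "truth.tsv"))
frame <- nuc_frame()

# classify each planted tandem with its first GAT center anchored at the
# bp nearest SHL5.5 (the placement resolved by the structural analysis)
anchor <- frame$dyad_index + as.integer(round(5.5 * frame$period)) - 1L
planted <- truth[!is.na(truth$spacer), ]
geo <- do.call(rbind, lapply(seq_len(nrow(planted)), function(i) {
  cl <- classify_tandem_geometry(anchor, planted$spacer[i], frame)
  data.frame(id = planted$id[i], class_label = planted$class_label[i],
             spacer = planted$spacer[i], delta_shl = cl$delta_shl,
             category = cl$category)
}))
write_table(geo, "results/geometry.tsv")
cat("geometry calls by class and spacer:\n")
print(table(geo$class_label, geo$spacer, geo$category))

template <- make_widom601_synthetic(frame = frame)
cat("\ntemplate: 145 bp,", nrow(scan_gat(template)), "intrinsic GATs\n")

series <- c(design_insertion_series(template, frame, 2),
            design_insertion_series(template, frame, 5))
s5e <- design_shl5e(template, frame)
sg <- scan_gat(s5e$sequence)
lab <- shl_label(sg$start + 1L, frame)
cat("SHL5e GAT positions (nearest half-integer SHL):",
    paste(lab, collapse = ", "), "\n")
cat("SHL5.5-SHL6.5 spacer:",
    sg$start[lab == 6.5] - sg$start[lab == 5.5] - 3L, "bp\n")

kos <- lapply(sg$start[lab %in% c(5, 5.5, 6.5)], function(s) {
  knockout_gat(s5e$sequence, s, name = sprintf("SHL5e_dSHL%g",
                                               shl_label(s + 1L, frame)))
})
all_cons <- c(list(template_synthetic = list(name = "template",
                                             sequence = template,
                                             edits = NULL)),
              series, list(SHL5e_tandem = s5e),
              setNames(kos, sapply(kos, `[[`, "name")))
write_fasta(as_genome(vapply(all_cons, `[[`, "", "sequence")),
            "results/constructs_synthetic.fa")
cat("wrote", length(all_cons), "construct sequences",
    "to results/constructs_synthetic.fa\n")
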