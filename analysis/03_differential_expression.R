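# Stage 3: the six pairwise treatment-group contrasts (C1-C6), the
# two-factor vapor x drinking model with interaction, and the overlap of
# significant probeset sets across the CIE-Drinking comparisons.
source("analysis/00_config.R")

norm <- read_expression(file.path(RESULTS, "expression_normalized.tsv"))
ann <- readr::read_csv(file.path(DATA_DIR, "annotation.csv"), show_col_types = FALSE)

de <- pairwise_contrasts(norm, ann)
tf <- two_factor_model(norm, ann)
write_stage(de, "de_contrasts.tsv")
write_stage(tf, "de_two_factor.tsv")

counts <- dplyr::summarise(dplyr::group_by(de, contrast),
                           n_sig_fdr01 = sum(fdr <= 0.01), .groups = "drop")
write_stage(counts, "de_counts.tsv")
message("significant probesets per contrast (FDR <= 0.01):")
for (i in seq_len(nrow(counts))) {
  message(sprintf("  %s: %d", counts$contrast[i], counts$n_sig_fdr01[i]))
}

ov <- contrast_overlap(de, fdr = 0.01)
write_stage(ov, "de_overlap.tsv")
tri <- ov$n_overlap[ov$contrasts == "C1&C3&C4"]
message(sprintf("probesets shared by C1, C3 and C4 (all CIE-Drinking comparisons): %d", tri))
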