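# Stage 6: derive drinking traits (weekly baseline means b1-b6, per-cycle
# means t1-t4, changes from baseline) and correlate module eigengenes and
# individual probesets with them by Spearman rank correlation.
source("analysis/00_config.R")

drinking <- readr::read_csv(file.path(DATA_DIR, "drinking.csv"), show_col_types = FALSE)
ann <- readr::read_csv(file.path(DATA_DIR, "annotation.csv"), show_col_types = FALSE)
norm <- read_expression(file.path(RESULTS, "expression_normalized.tsv"))
universe <- read_stage("anova_universe.tsv")$probeset
eig_tbl <- read_stage("eigengenes.tsv")
eig <- as.matrix(eig_tbl[, -1])
rownames(eig) <- eig_tbl$module

traits <- derive_traits(drinking)
write_stage(traits, "traits.tsv")

smap <- ann[, c("sample_id", "mouse_id", "drinking")]
ec <- correlate_eigengenes(eig, traits, smap)
gc_ <- correlate_genes(norm[universe, ], traits, smap,
                       trait_cols = c("t4", "abs_change_4", "pct_change_4"))
write_stage(ec, "eigengene_trait_correlation.tsv")
write_stage(gc_, "gene_trait_correlation.tsv")

c4 <- ec[ec$trait == "abs_change_4", ]
c4 <- c4[order(c4$p_value), ]
message("module eigengene vs cycle-4 change from baseline:")
for (i in seq_len(nrow(c4))) {
  message(sprintf("  %-10s rho %6.2f  p %.2g", c4$unit[i], c4$rho[i], c4$p_value[i]))
}
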