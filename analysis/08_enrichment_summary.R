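# Stage 8: hypergeometric over-representation of the DE contrast lists in
# each module, and the combined per-module summary (disruption, cycle-4
# trait correlation, DE over-representation).
source("analysis/00_config.R")

universe <- read_stage("anova_universe.tsv")$probeset
assign <- with(read_stage("modules.tsv"), setNames(module, probeset))
de <- read_stage("de_contrasts.tsv")
val <- read_stage("module_validation.tsv")
ec <- read_stage("eigengene_trait_correlation.tsv")
dis <- read_stage("module_disruption.tsv")

de_lists <- split(de$probeset[de$fdr <= 0.01], de$contrast[de$fdr <= 0.01])
de_lists <- lapply(de_lists, intersect, y = universe)
de_lists <- de_lists[vapply(de_lists, length, integer(1)) > 0]
enr <- module_list_enrichment(assign, de_lists, universe,
                              correction = "BH", threshold = 0.05)
write_stage(enr, "module_de_enrichment.tsv")

summary_tbl <- module_summary(assign, val, ec, dis, enr, trait_p = 0.01)
write_stage(summary_tbl, "module_summary.tsv")

message("combined module summary:")
for (i in seq_len(nrow(summary_tbl))) {
  s <- summary_tbl[i, ]
  message(sprintf("  %-10s size %4d  %s%s%s",
                  s$module, s$size,
                  ifelse(s$disrupted, "[disrupted] ", ""),
                  ifelse(s$trait_correlated, "[cycle-4 correlated] ", ""),
                  ifelse(s$de_overrepresented, "[DE over-represented]", "")))
}
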