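# Stage 5: permutation validation of module coherence -- observed mean
# intra-module topological overlap vs 100 same-size random gene sets.
source("analysis/00_config.R")

tom <- readRDS(file.path("scratch", "tom.rds"))
assign <- with(read_stage("modules.tsv"), setNames(module, probeset))

val <- validate_modules(tom, assign, n_perm = 100,
                        seed = derive_seed(MASTER_SEED, "validation"))
write_stage(val, "module_validation.tsv")

for (i in seq_len(nrow(val))) {
  message(sprintf("  %-10s size %4d  Z %8.1f  FDR %.3g  %s",
                  val$module[i], val$size[i],
                  ifelse(is.na(val$Z[i]), NA, val$Z[i]), val$fdr[i],
                  ifelse(val$validated[i], "validated", "-")))
}
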