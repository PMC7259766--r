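# Stage 1: generate the synthetic study -- daily drinking records for the
# four treatment groups and a log2 expression matrix with planted module,
# trait-linkage, differential-expression and disruption structure.
source("analysis/00_config.R")

cfg <- study_sim_config()
drinking <- simulate_drinking(cfg)
sim <- simulate_expression(cfg, drinking)

write_expression(sim$expr, file.path(DATA_DIR, "expression.tsv"))
readr::write_csv(sim$ann, file.path(DATA_DIR, "annotation.csv"))
readr::write_csv(drinking, file.path(DATA_DIR, "drinking.csv"))
write_stage(tibble::tibble(probeset = names(sim$truth$module_of_gene),
                           module = unname(sim$truth$module_of_gene),
                           de = names(sim$truth$module_of_gene) %in%
                             sim$truth$de_genes),
            "data", "ground_truth.tsv")

cd <- drinking[drinking$group == "CIE Drinking", ]
esc <- mean(vapply(split(cd, cd$mouse_id), function(x) {
  mean(x$intake_gkg[x$phase == "cie4"]) -
    mean(x$intake_gkg[grepl("^baseline", x$phase)])
}, numeric(1)))
message(sprintf("simulated %d probesets x %d arrays; %d drinking mice over 50 sessions",
                nrow(sim$expr), ncol(sim$expr),
                length(unique(drinking$mouse_id[drinking$drinking == "Drinking"]))))
message(sprintf("CIE-Drinking cycle-4 escalation over baseline: %.2f g/kg (configured %.2f)",
                esc, cfg$cie_escalation[4]))
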