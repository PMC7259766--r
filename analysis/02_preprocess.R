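# Stage 2: quantile-normalize the expression matrix and select the network
# input universe by four-group one-way ANOVA at FDR <= 0.01.
source("analysis/00_config.R")

expr <- read_expression(file.path(DATA_DIR, "expression.tsv"))
ann <- readr::read_csv(file.path(DATA_DIR, "annotation.csv"), show_col_types = FALSE)

norm <- quantile_normalize(expr)
write_expression(norm, file.path(RESULTS, "expression_normalized.tsv"))

universe <- anova_filter(norm, ann, fdr_threshold = 0.01)
write_stage(tibble::tibble(probeset = universe), "anova_universe.tsv")

truth <- read_stage("data", "ground_truth.tsv")
tab <- table(truth$module[match(universe, truth$probeset)])
message(sprintf("%d of %d probesets pass the ANOVA filter", length(universe), nrow(norm)))
message("universe composition: ", paste(names(tab), tab, sep = "=", collapse = ", "))
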