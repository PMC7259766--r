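# Stage 4: soft-threshold selection, unsigned TOM network over the ANOVA
# universe, module detection, eigengenes and connectivity statistics.
source("analysis/00_config.R")

norm <- read_expression(file.path(RESULTS, "expression_normalized.tsv"))
universe <- read_stage("anova_universe.tsv")$probeset
m <- norm[universe, ]

pst <- pick_soft_threshold(m, candidate_powers = c(1:10, 12, 14, 16))
write_stage(pst$fit_table, "soft_threshold_scan.tsv")
message(sprintf("scale-free scan suggests power %d; using the study value 6",
                pst$power))

ncfg <- study_network_config()
a <- adjacency(m, ncfg)
tom <- topological_overlap(a)
assign <- detect_modules(tom, ncfg)
eig <- module_eigengenes(m, assign)
con <- connectivity_stats(a, assign, eig, m)

write_stage(tibble::tibble(probeset = names(assign), module = unname(assign)),
            "modules.tsv")
write_stage(tibble::as_tibble(eig, rownames = "module"), "eigengenes.tsv")
write_stage(con, "connectivity.tsv")
saveRDS(tom, file.path("scratch", "tom.rds"))  # large; scratch only

sizes <- sort(table(assign[assign != "grey"]), decreasing = TRUE)
message(sprintf("%d modules (plus %d grey genes): %s",
                length(sizes), sum(assign == "grey"),
                paste(names(sizes), sizes, sep = "=", collapse = ", ")))
truth <- read_stage("data", "ground_truth.tsv")
ari <- adjusted_rand_index(truth$module[match(universe, truth$probeset)],
                           assign[universe])
message(sprintf("adjusted Rand index vs planted modules (over the universe): %.3f", ari))
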