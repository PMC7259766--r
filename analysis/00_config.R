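# Shared settings for the analysis workflow. Each numbered script is a thin
# driver over the cienet package: run them in order from the repository root.
library(cienet)

MASTER_SEED <- 20260928
RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")

# study conditions: 4 treatment groups x 12 mice, ~2,500 probesets with five
# planted coexpression modules; module 1 tracks cycle-4 drinking escalation,
# module 2 loses its coexpression structure in the CIE-Drinking group
study_sim_config <- function() sim_config(seed = MASTER_SEED)

study_network_config <- function() network_config(power = 6, deep_split = 2)

dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create("scratch", showWarnings = FALSE)

read_stage <- function(...) readr::read_tsv(file.path(RESULTS, ...),
                                            show_col_types = FALSE)
write_stage <- function(x, ...) readr::write_tsv(x, file.path(RESULTS, ...))
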