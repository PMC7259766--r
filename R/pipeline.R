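#' Pipeline configuration
#'
#' Bundles either a simulation block or input paths with the per-stage
#' thresholds and the network configuration. All resampling draws its
#' randomness from the single `seed` via fixed per-stage derivations
#' ([derive_seed()]).
#'
#' @param simulate A [sim_config()], or `NULL` to read files instead.
#' @param expr_path,ann_path,drinking_path Input paths (TSV expression, CSV
#'   annotation, CSV drinking record) when not simulating.
#' @param network A [network_config()].
#' @param de_fdr,anova_fdr,validate_fdr,enrich_fdr,trait_p,disrupt_z
#'   Stage thresholds (defaults 0.01, 0.01, 0.2, 0.05, 0.01, -2).
#' @param n_perm Random pseudo-modules for validation (default 100).
#' @param n_boot Bootstrap networks for disruption (default 200).
#' @param seed Master seed (mandatory; every resampling stage derives from it).
#' @return A `cie_pipeline_config` list.
#' @export
pipeline_config <- function(simulate = sim_config(), expr_path = NULL,
                            ann_path = NULL, drinking_path = NULL,
                            network = network_config(),
                            de_fdr = 0.01, anova_fdr = 0.01,
                            validate_fdr = 0.2, enrich_fdr = 0.05,
                            trait_p = 0.01, disrupt_z = -2,
                            n_perm = 100, n_boot = 200, seed = 1L) {
  if (is.null(simulate) &&
      (is.null(expr_path) || is.null(ann_path) || is.null(drinking_path))) {
    stop_cfg("provide either a simulate block or all three input paths")
  }
  for (thr in c(de_fdr, anova_fdr, validate_fdr, enrich_fdr, trait_p)) {
    if (thr < 0 || thr > 1) stop_cfg("FDR/p thresholds must lie in [0, 1]")
  }
  structure(list(simulate = simulate, expr_path = expr_path,
                 ann_path = ann_path, drinking_path = drinking_path,
                 network = network, de_fdr = de_fdr, anova_fdr = anova_fdr,
                 validate_fdr = validate_fdr, enrich_fdr = enrich_fdr,
                 trait_p = trait_p, disrupt_z = disrupt_z,
                 n_perm = n_perm, n_boot = n_boot, seed = as.integer(seed)),
            class = "cie_pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_cfg("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, quantile normalization and ANOVA probeset
#' selection, the six pairwise contrasts and the two-factor model, drinking
#' trait derivation, network construction and module detection, permutation
#' module validation, eigengene- and probeset-trait correlation, bootstrap
#' module-disruption Z statistics, and module-by-DE-list enrichment, writing
#' each stage's table under `outdir` plus a combined per-module summary
#' (disrupted? trait-correlated at the cycle-4 change? over-represented for
#' treatment-responsive genes?). Reruns with the same config and seed are
#' byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list of the stage results (paths in `$paths`).
#' @export
run_pipeline <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "cie_pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  log_lines <- c(
    sprintf("cienet %s | R %s", as.character(utils::packageVersion("cienet")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", cfg$seed)
  )

  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim_cfg <- cfg$simulate
    sim_cfg$seed <- cfg$seed
    sim_cfg <- validate_sim_config(sim_cfg)
    drinking <- run_stage("simulate", simulate_drinking(sim_cfg))
    sim <- run_stage("simulate", simulate_expression(sim_cfg, drinking))
    expr <- sim$expr; ann <- sim$ann; truth <- sim$truth
    write_expression(expr, pth("expression.tsv"))
    readr::write_csv(ann, pth("annotation.csv"))
    readr::write_csv(drinking, pth("drinking.csv"))
    readr::write_tsv(tibble::tibble(
      probeset = names(truth$module_of_gene),
      module = unname(truth$module_of_gene),
      de = names(truth$module_of_gene) %in% truth$de_genes
    ), pth("ground_truth.tsv"))
  } else {
    expr <- run_stage("ingest", read_expression(cfg$expr_path))
    ann <- run_stage("ingest", readr::read_csv(cfg$ann_path, show_col_types = FALSE))
    drinking <- run_stage("ingest", readr::read_csv(cfg$drinking_path, show_col_types = FALSE))
  }

  norm <- run_stage("preprocess", quantile_normalize(expr))
  universe <- run_stage("preprocess", anova_filter(norm, ann, cfg$anova_fdr))
  readr::write_tsv(tibble::tibble(probeset = universe), pth("anova_universe.tsv"))
  if (length(universe) < 2 * cfg$network$min_module_size) {
    stop_cfg("pipeline stage 'preprocess' failed: only %d probesets pass the ANOVA filter",
             length(universe))
  }

  de <- run_stage("de", pairwise_contrasts(norm, ann))
  tf <- run_stage("de", two_factor_model(norm, ann))
  readr::write_tsv(de, pth("de_contrasts.tsv"))
  readr::write_tsv(tf, pth("de_two_factor.tsv"))
  readr::write_tsv(run_stage("de", contrast_overlap(de, cfg$de_fdr)),
                   pth("de_overlap.tsv"))

  traits <- run_stage("traits", derive_traits(drinking))
  readr::write_tsv(traits, pth("traits.tsv"))

  net_m <- norm[universe, , drop = FALSE]
  a <- run_stage("network", adjacency(net_m, cfg$network))
  tom <- run_stage("network", topological_overlap(a))
  assign <- run_stage("network", detect_modules(tom, cfg$network))
  eig <- run_stage("network", module_eigengenes(net_m, assign))
  con <- run_stage("network", connectivity_stats(a, assign, eig, net_m))
  readr::write_tsv(tibble::tibble(probeset = names(assign), module = unname(assign)),
                   pth("modules.tsv"))
  eig_out <- tibble::as_tibble(eig, rownames = "module")
  readr::write_tsv(eig_out, pth("eigengenes.tsv"))
  readr::write_tsv(con, pth("connectivity.tsv"))

  val <- run_stage("validation", validate_modules(
    tom, assign, n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, "validation"),
    fdr_threshold = cfg$validate_fdr))
  readr::write_tsv(val, pth("module_validation.tsv"))

  smap <- ann[, intersect(c("sample_id", "mouse_id", "drinking"), names(ann))]
  ec <- run_stage("correlation", correlate_eigengenes(eig, traits, smap))
  gc_ <- run_stage("correlation", correlate_genes(net_m, traits, smap))
  readr::write_tsv(ec, pth("eigengene_trait_correlation.tsv"))
  readr::write_tsv(gc_, pth("gene_trait_correlation.tsv"))

  dis <- run_stage("disruption", disruption_z(
    norm, ann, "CIE Drinking", "Air NonDrinking", assign, cfg$network,
    n_boot = cfg$n_boot, seed = derive_seed(cfg$seed, "disruption"),
    z_threshold = cfg$disrupt_z))
  readr::write_tsv(dis, pth("module_disruption.tsv"))

  de_lists <- split(de$probeset[de$fdr <= cfg$de_fdr],
                    de$contrast[de$fdr <= cfg$de_fdr])
  de_lists <- lapply(de_lists, intersect, y = universe)
  de_lists <- de_lists[vapply(de_lists, length, integer(1)) > 0]
  enr <- NULL
  if (length(de_lists)) {
    enr <- run_stage("enrichment", module_list_enrichment(
      assign, de_lists, universe, correction = "BH", threshold = cfg$enrich_fdr))
    readr::write_tsv(enr, pth("module_de_enrichment.tsv"))
  }

  summary_tbl <- run_stage("summary", module_summary(
    assign, val, ec, dis, enr, trait_p = cfg$trait_p))
  readr::write_tsv(summary_tbl, pth("module_summary.tsv"))

  if (!is.null(truth)) {
    planted <- truth$module_of_gene[universe]
    recovery <- tibble::tibble(
      metric = c("ari_vs_planted", "n_modules_detected", "n_universe"),
      value = c(adjusted_rand_index(planted, assign[universe]),
                length(setdiff(unique(assign), "grey")), length(universe))
    )
    readr::write_tsv(recovery, pth("recovery.tsv"))
  }

  cfg_txt <- utils::capture.output(utils::str(cfg, give.attr = FALSE))
  writeLines(cfg_txt, pth("config.txt"))
  log_lines <- c(log_lines,
                 sprintf("config md5: %s", unname(tools::md5sum(pth("config.txt")))),
                 sprintf("stage seeds: validation=%d disruption=%d",
                         derive_seed(cfg$seed, "validation"),
                         derive_seed(cfg$seed, "disruption")))
  writeLines(log_lines, pth("run_log.txt"))

  invisible(list(expr = expr, ann = ann, drinking = drinking, truth = truth,
                 universe = universe, de = de, two_factor = tf, traits = traits,
                 assign = assign, eigengenes = eig, connectivity = con,
                 validation = val, eigengene_traits = ec, gene_traits = gc_,
                 disruption = dis, enrichment = enr, summary = summary_tbl,
                 outdir = outdir))
}

#' Combined per-module summary
#'
#' Joins validation, disruption, cycle-4 trait correlation and DE
#' over-representation into one row per module: the triple used to shortlist
#' ethanol-responsive modules.
#'
#' @param assign Module assignment.
#' @param val Output of [validate_modules()].
#' @param ec Eigengene-trait correlations ([correlate_eigengenes()]).
#' @param dis Output of [disruption_z()].
#' @param enr Output of [module_list_enrichment()] on DE lists (or `NULL`).
#' @param trait_p p-value cutoff for calling a module trait-correlated.
#' @return Tibble with one row per non-grey module.
#' @export
module_summary <- function(assign, val, ec, dis, enr, trait_p = 0.01) {
  mods <- setdiff(unique(assign), "grey")
  rows <- lapply(mods, function(mod) {
    v <- val[val$module == mod, ]
    d <- dis[dis$module == mod, ]
    e4 <- ec[ec$unit == mod & ec$trait == "abs_change_4", ]
    de_hit <- FALSE
    if (!is.null(enr) && "C4" %in% enr$list) {
      de_hit <- isTRUE(enr$significant[enr$module == mod & enr$list == "C4"])
    }
    tibble::tibble(
      module = mod, size = sum(assign == mod),
      validated = isTRUE(v$validated[1]),
      Z_cor.kIM = if (nrow(d)) d$Z_cor.kIM[1] else NA_real_,
      disrupted = isTRUE(d$disrupted[1]),
      trait_rho_cycle4 = if (nrow(e4)) e4$rho[1] else NA_real_,
      trait_correlated = nrow(e4) > 0 && !is.na(e4$p_value[1]) && e4$p_value[1] < trait_p,
      de_overrepresented = de_hit
    )
  })
  dplyr::bind_rows(rows)
}

#' @importFrom tools md5sum
NULL
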