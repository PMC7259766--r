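#' Simulation configuration for a synthetic CIE expression study
#'
#' Defines the study conditions emulated by the generator: a 2x2 vapor-by-
#' drinking design with four treatment groups, a baseline-then-CIE drinking
#' schedule, planted coexpression modules driven by latent factors, optional
#' drinking-linked module eigengenes, group mean-shift (differential
#' expression) effects, and group-specific connectivity disruption.
#'
#' Defaults mirror the emulated study: n = 12 mice per group, six baseline
#' weeks of five drinking days followed by four CIE cycles of five drinking
#' days, baseline intake near 2.2 g/kg with the CIE-Drinking group escalating
#' across cycles (dipping at cycle 2) and the Air-Drinking group increasing
#' modestly, and a few thousand probesets organized into planted modules.
#'
#' @param n_genes Total number of probesets.
#' @param module_sizes Integer vector of planted module sizes (each >= 3);
#'   remaining genes are uncorrelated background. May be empty.
#' @param n_per_group Mice (= arrays) per treatment group.
#' @param loading_range Interval in `[0, 1]` from which factor loadings are
#'   drawn uniformly.
#' @param noise_sd Residual standard deviation on the log2 scale.
#' @param de_effect Log2 mean shift applied to differentially expressed genes.
#' @param n_de_genes Number of background genes receiving the mean shift.
#' @param de_group Treatment group carrying the mean shift.
#' @param trait_linked_modules Named numeric vector mapping module name to the
#'   target population Spearman correlation between its factor and the
#'   cycle-4 change-from-baseline drinking trait.
#' @param disrupted_modules Named list mapping module name to
#'   `list(group =, fraction =)`: within that group, that fraction of member
#'   genes loses its shared-factor structure.
#' @param module_group_effect Mean offset (in factor SD units) added to each
#'   non-trait-linked module's factor in one treatment group (rotating across
#'   groups by module index), making planted modules treatment-responsive.
#' @param baseline_mean Mean baseline intake, g/kg per 2-h session.
#' @param cie_escalation,air_escalation Per-cycle additive intake increases
#'   (g/kg) over baseline for the CIE-Drinking and Air-Drinking groups.
#' @param daily_sd Day-to-day intake SD (g/kg).
#' @param mouse_intercept_sd,mouse_escalation_sd SDs of per-mouse baseline and
#'   CIE-response random effects (g/kg).
#' @param seed Master RNG seed for the generator.
#' @return A `cie_sim_config` list.
#' @export
sim_config <- function(n_genes = 2500,
                       module_sizes = c(300L, 250L, 200L, 150L, 100L),
                       n_per_group = 12L,
                       loading_range = c(0.2, 0.95),
                       noise_sd = 0.5,
                       de_effect = 1,
                       n_de_genes = 200L,
                       de_group = "CIE Drinking",
                       trait_linked_modules = c(M1 = 0.7),
                       disrupted_modules = list(
                         M2 = list(group = "CIE Drinking", fraction = 0.8)
                       ),
                       module_group_effect = 2,
                       baseline_mean = 2.2,
                       cie_escalation = c(0.7, 0.3, 1.0, 1.3),
                       air_escalation = c(0.3, 0.3, 0.4, 0.4),
                       daily_sd = 0.5,
                       mouse_intercept_sd = 0.3,
                       mouse_escalation_sd = 0.3,
                       seed = 1L) {
  module_sizes <- as.integer(module_sizes)
  cfg <- list(
    n_genes = as.integer(n_genes), module_sizes = module_sizes,
    n_modules = length(module_sizes),
    module_names = if (length(module_sizes)) paste0("M", seq_along(module_sizes)) else character(0),
    n_per_group = as.integer(n_per_group),
    loading_range = as.numeric(loading_range), noise_sd = noise_sd,
    de_effect = de_effect, n_de_genes = as.integer(n_de_genes),
    de_group = de_group,
    trait_linked_modules = trait_linked_modules,
    disrupted_modules = disrupted_modules,
    module_group_effect = module_group_effect,
    baseline_mean = baseline_mean,
    cie_escalation = cie_escalation, air_escalation = air_escalation,
    daily_sd = daily_sd, mouse_intercept_sd = mouse_intercept_sd,
    mouse_escalation_sd = mouse_escalation_sd,
    n_baseline_weeks = 6L, n_cycles = 4L, days_per_phase = 5L,
    seed = as.integer(seed)
  )
  class(cfg) <- "cie_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_per_group < 2) stop_cfg("n_per_group must be >= 2")
  if (length(cfg$module_sizes) && any(cfg$module_sizes < 3)) {
    stop_cfg("each module size must be >= 3")
  }
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    stop_cfg("sum(module_sizes) = %d exceeds n_genes = %d",
             sum(cfg$module_sizes), cfg$n_genes)
  }
  if (length(cfg$loading_range) != 2 || any(cfg$loading_range < 0) ||
      any(cfg$loading_range > 1) || diff(cfg$loading_range) < 0) {
    stop_cfg("loading_range must be an increasing interval within [0, 1]")
  }
  if (!cfg$de_group %in% group_levels()) stop_cfg("unknown de_group '%s'", cfg$de_group)
  if (cfg$n_de_genes > cfg$n_genes - sum(cfg$module_sizes)) {
    stop_cfg("n_de_genes exceeds the number of background genes")
  }
  bad <- setdiff(names(cfg$trait_linked_modules), cfg$module_names)
  if (length(bad)) stop_cfg("trait_linked_modules names unknown: %s", paste(bad, collapse = ", "))
  if (any(abs(cfg$trait_linked_modules) >= 1)) {
    stop_cfg("trait rho targets must lie in (-1, 1)")
  }
  for (nm in names(cfg$disrupted_modules)) {
    d <- cfg$disrupted_modules[[nm]]
    if (!nm %in% cfg$module_names) stop_cfg("disrupted module '%s' unknown", nm)
    if (!d$group %in% group_levels()) stop_cfg("disruption group '%s' unknown", d$group)
    if (d$fraction < 0 || d$fraction > 1) stop_cfg("disruption fraction must be in [0, 1]")
  }
  if (length(cfg$cie_escalation) != cfg$n_cycles ||
      length(cfg$air_escalation) != cfg$n_cycles) {
    stop_cfg("escalation vectors must have one entry per CIE cycle")
  }
  cfg
}

sim_mice <- function(cfg) {
  groups <- rep(group_levels(), each = cfg$n_per_group)
  n <- length(groups)
  tibble::tibble(
    mouse_id = sprintf("m%02d", seq_len(n)),
    group = groups,
    vapor = ifelse(grepl("^CIE", groups), "CIE", "Air"),
    drinking = ifelse(grepl("NonDrinking$", groups), "NonDrinking", "Drinking")
  )
}

#' Simulate daily two-bottle-choice drinking records
#'
#' Drinking mice get six baseline weeks then four CIE cycles of five daily
#' sessions each; daily intake is phase mean plus Gaussian noise truncated at
#' zero. The CIE-Drinking group escalates across cycles; the Air-Drinking
#' group increases modestly; NonDrinking mice are identically zero.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with mouse_id, group, vapor, drinking, session, phase,
#'   intake_gkg; 50 sessions per mouse.
#' @export
simulate_drinking <- function(cfg) {
  stopifnot(inherits(cfg, "cie_sim_config"))
  mice <- sim_mice(cfg)
  d <- cfg$days_per_phase
  phases <- c(rep(paste0("baseline", seq_len(cfg$n_baseline_weeks)), each = d),
              rep(paste0("cie", seq_len(cfg$n_cycles)), each = d))
  n_sess <- length(phases)
  withr::with_seed(derive_seed(cfg$seed, "drinking"), {
    recs <- lapply(seq_len(nrow(mice)), function(i) {
      mi <- mice[i, ]
      if (mi$drinking == "NonDrinking") {
        intake <- rep(0, n_sess)
      } else {
        b_i <- rnorm(1, 0, cfg$mouse_intercept_sd)
        s_i <- rnorm(1, 0, cfg$mouse_escalation_sd)
        esc <- if (mi$vapor == "CIE") cfg$cie_escalation else cfg$air_escalation
        phase_mean <- c(rep(cfg$baseline_mean + b_i, cfg$n_baseline_weeks * d),
                        rep(cfg$baseline_mean + b_i + esc + s_i, each = d))
        intake <- pmax(0, phase_mean + rnorm(n_sess, 0, cfg$daily_sd))
      }
      tibble::tibble(
        mouse_id = mi$mouse_id, group = mi$group, vapor = mi$vapor,
        drinking = mi$drinking, session = seq_len(n_sess), phase = phases,
        intake_gkg = intake
      )
    })
    dplyr::bind_rows(recs)
  })
}

# cycle-4 change from baseline per mouse, zero for NonDrinking animals
cycle4_change <- function(drinking) {
  agg <- dplyr::summarise(
    dplyr::group_by(drinking, .data$mouse_id),
    base = mean(.data$intake_gkg[grepl("^baseline", .data$phase)]),
    t4 = mean(.data$intake_gkg[.data$phase == "cie4"]),
    nondrink = .data$drinking[1] == "NonDrinking",
    .groups = "drop"
  )
  setNames(ifelse(agg$nondrink, 0, agg$t4 - agg$base), agg$mouse_id)
}

# Monte-Carlo calibration of the trait-blend weight: find a such that the
# expected sample Spearman of a*s + sqrt(1-a^2)*z with the trait hits rho.
calibrate_trait_loading <- function(trait, rho_target, n_mc = 2000L) {
  n <- length(trait)
  tr <- rank(trait)
  s <- as.numeric(scale(rank(trait)))
  z <- matrix(rnorm(n * n_mc), n, n_mc)
  exp_rho <- function(a) {
    f <- a * s + sqrt(1 - a^2) * z
    fr <- apply(f, 2, rank)
    mean(cor(fr, tr))
  }
  if (rho_target == 0) return(0)
  f_lo <- exp_rho(0) - rho_target
  f_hi <- exp_rho(0.9999) - rho_target
  if (sign(f_lo) == sign(f_hi)) {
    stop_cfg("trait rho target %.2f is not attainable for this trait vector", rho_target)
  }
  uniroot(function(a) exp_rho(a) - rho_target, c(0, 0.9999), tol = 1e-4)$root
}

#' Simulate a log2 expression matrix with planted module structure
#'
#' Gene g in module q follows `x = mu_g + lambda_g * f_q + delta_g * I(group
#' in affected) + eps`; loadings are uniform on `loading_range`, factors are
#' standardized across samples. Trait-linked module factors are monotone
#' blends of the mouse's cycle-4 change-from-baseline intake and independent
#' noise, calibrated by Monte Carlo so the population Spearman correlation
#' hits the configured target. For disrupted modules, within the designated
#' group the designated fraction of member genes exchanges its shared-factor
#' contribution for an independently re-drawn loading on an independent
#' per-gene factor, which genuinely breaks within-module correlation in that
#' group only (sign randomization alone is invisible to an unsigned,
#' magnitude-based network). Background genes are pure noise.
#'
#' @param cfg A [sim_config()].
#' @param drinking Output of [simulate_drinking()] under the same config.
#' @return List with `expr` (genes x samples log2 matrix), `ann` (sample
#'   annotation tibble), and `truth` (planted ground truth).
#' @export
simulate_expression <- function(cfg, drinking = simulate_drinking(cfg)) {
  stopifnot(inherits(cfg, "cie_sim_config"))
  mice <- sim_mice(cfg)
  n_samp <- nrow(mice)
  ann <- tibble::tibble(
    sample_id = paste0("s_", mice$mouse_id), mouse_id = mice$mouse_id,
    vapor = mice$vapor, drinking = mice$drinking,
    region = "SIM", batch = "batch1"
  )
  grp <- sample_groups(ann)
  trait <- cycle4_change(drinking)[mice$mouse_id]

  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  module_of <- rep("background", cfg$n_genes)
  idx <- 0L
  mod_idx <- list()
  for (q in seq_len(cfg$n_modules)) {
    sel <- idx + seq_len(cfg$module_sizes[q])
    module_of[sel] <- cfg$module_names[q]
    mod_idx[[cfg$module_names[q]]] <- sel
    idx <- idx + cfg$module_sizes[q]
  }
  names(module_of) <- gene_ids

  withr::with_seed(derive_seed(cfg$seed, "expression"), {
    mu <- rnorm(cfg$n_genes, 8, 0.5)
    x <- matrix(rnorm(cfg$n_genes * n_samp, 0, cfg$noise_sd),
                cfg$n_genes, n_samp, dimnames = list(gene_ids, ann$sample_id))
    x <- x + mu

    factors <- matrix(0, cfg$n_modules, n_samp)
    for (q in seq_len(cfg$n_modules)) {
      nm <- cfg$module_names[q]
      if (nm %in% names(cfg$trait_linked_modules)) {
        rho <- cfg$trait_linked_modules[[nm]]
        a <- calibrate_trait_loading(trait, abs(rho))
        s <- as.numeric(scale(rank(trait)))
        f <- sign(rho) * a * s + sqrt(1 - a^2) * rnorm(n_samp)
      } else {
        f <- rnorm(n_samp)
        target_grp <- group_levels()[((q - 1) %% 4) + 1]
        f <- f + cfg$module_group_effect * (grp == target_grp)
      }
      factors[q, ] <- as.numeric(scale(f))
    }

    lam <- runif(cfg$n_genes, cfg$loading_range[1], cfg$loading_range[2])
    for (q in seq_len(cfg$n_modules)) {
      sel <- mod_idx[[q]]
      x[sel, ] <- x[sel, ] + lam[sel] %o% factors[q, ]
    }

    # group-specific connectivity disruption
    disrupted_genes <- list()
    for (nm in names(cfg$disrupted_modules)) {
      d <- cfg$disrupted_modules[[nm]]
      sel <- mod_idx[[nm]]
      n_dis <- floor(d$fraction * length(sel))
      if (n_dis == 0) next
      dis <- sort(sample(sel, n_dis))
      disrupted_genes[[nm]] <- gene_ids[dis]
      in_grp <- which(grp == d$group)
      lam_new <- runif(n_dis, cfg$loading_range[1], cfg$loading_range[2]) *
        sample(c(-1, 1), n_dis, replace = TRUE)
      own <- matrix(rnorm(n_dis * length(in_grp)), n_dis, length(in_grp))
      q <- match(nm, cfg$module_names)
      x[dis, in_grp] <- x[dis, in_grp] -
        lam[dis] %o% factors[q, in_grp] + lam_new * own
    }

    # differential expression: mean shift in one treatment cell
    de_genes <- character(0)
    if (cfg$n_de_genes > 0 && cfg$de_effect != 0) {
      bg <- which(module_of == "background")
      de_sel <- sort(sample(bg, cfg$n_de_genes))
      de_genes <- gene_ids[de_sel]
      x[de_sel, grp == cfg$de_group] <- x[de_sel, grp == cfg$de_group] + cfg$de_effect
    }
  })

  de_per_contrast <- lapply(contrast_table()$contrast, function(cc) {
    pair <- contrast_groups(cc)
    if (cfg$de_group %in% pair) de_genes else character(0)
  })
  names(de_per_contrast) <- contrast_table()$contrast

  truth <- list(
    module_of_gene = module_of,
    de_genes = de_genes,
    de_group = cfg$de_group,
    de_genes_per_contrast = de_per_contrast,
    trait_rho_planted = cfg$trait_linked_modules,
    disrupted = lapply(cfg$disrupted_modules, `[[`, "group"),
    disrupted_genes = disrupted_genes,
    trait = trait
  )
  list(expr = x, ann = ann, truth = truth)
}

#' @importFrom stats uniroot
NULL
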