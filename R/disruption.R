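# per-module connectivity vectors (kIM, and kME by the requested mode) for
# one sample subset, touching only within-module adjacency blocks
subset_connectivity <- function(m, samp_idx, assign, cfg,
                                kme_mode = "eigengene", full_a = NULL) {
  mods <- setdiff(unique(assign), "grey")
  kim <- list(); kme <- list()
  for (mod in mods) {
    genes <- names(assign)[assign == mod]
    sub <- m[genes, samp_idx, drop = FALSE]
    cr <- suppressWarnings(cor(t(sub)))
    cr[is.na(cr)] <- 0
    a <- if (cfg$sign == "unsigned") abs(cr)^cfg$power else ((1 + cr) / 2)^cfg$power
    diag(a) <- 1
    kim[[mod]] <- setNames(rowSums(a) - 1, genes)
    if (kme_mode == "eigengene") {
      xs <- t(scale(t(sub)))
      xs[is.na(xs)] <- 0
      e <- if (length(genes) == 1) as.numeric(xs) else svd(xs, nu = 0, nv = 1)$v[, 1]
      if (sum(abs(e)) == 0) e <- rep(1, ncol(sub))
      cm <- colMeans(xs)
      if (!anyNA(cm) && sd(cm) > 0 && sd(e) > 0 && cor(e, cm) < 0) e <- -e
      km <- suppressWarnings(as.numeric(cor(t(sub), e)))
      km[is.na(km)] <- 0
      kme[[mod]] <- setNames(km, genes)
    }
  }
  if (kme_mode == "ktotal") {
    # full-network row-sum connectivity on the subset samples
    a_full <- adjacency(m[, samp_idx, drop = FALSE], cfg)
    kt <- rowSums(a_full) - 1
    for (mod in mods) kme[[mod]] <- kt[names(assign)[assign == mod]]
  }
  list(kIM = kim, kME = kme)
}

#' Connectivity statistics within one treatment group
#'
#' Builds the adjacency from that group's samples only (same power as the
#' full network) and reports each gene's kTotal, kIM within its full-network
#' module, and kME against the module eigengene recomputed on the group's
#' samples.
#'
#' @param m Probesets x samples matrix.
#' @param ann Sample annotation.
#' @param group Treatment group label, or `"all"` for every sample.
#' @param assign Full-network module assignment.
#' @param cfg A [network_config()].
#' @return Tibble: probeset, module, kTotal, kIM, kME.
#' @export
group_connectivity <- function(m, ann, group, assign, cfg = network_config()) {
  check_expression_matrix(m)
  ann <- check_ann(m, ann)
  idx <- if (identical(group, "all")) seq_len(ncol(m)) else
    which(sample_groups(ann) == group)
  if (length(idx) < 4) stop_cfg("group '%s' has < 4 samples", group)
  a <- adjacency(m[, idx, drop = FALSE], cfg)
  sub_m <- m[, idx, drop = FALSE]
  eig <- module_eigengenes(sub_m, assign)
  connectivity_stats(a, assign, eig, sub_m)
}

#' Bootstrap Z statistics for module connectivity disruption
#'
#' Per module, the observed statistic is the Pearson correlation over member
#' genes between the kIM (and kME) vectors computed separately in two
#' treatment groups. The null is built from `n_boot` sample subsets drawn
#' without replacement ignoring group labels, each of size equal to the
#' smaller group; connectivity is computed per subset and the null mean and
#' SD are taken over the pairwise correlations between bootstrap networks
#' (subsampled to `max_pairs` pairs for tractability; a per-network-average
#' variant is available). `Z = (obs - mean) / sd`; a module is flagged
#' disrupted when `Z_cor_kIM <= z_threshold` (default -2).
#'
#' @param m Probesets x samples matrix.
#' @param ann Sample annotation.
#' @param group_a,group_b Treatment group labels to compare (the canonical
#'   comparison is CIE Drinking vs Air NonDrinking).
#' @param assign Full-network module assignment.
#' @param cfg A [network_config()].
#' @param n_boot Number of bootstrap networks (default 200).
#' @param seed RNG seed.
#' @param max_pairs Pairwise-correlation subsample size (default 2000).
#' @param null_stat `"pairwise"` (default) or `"network_mean"`.
#' @param pair_mode `"disjoint"` (default) restricts the null to bootstrap
#'   pairs sharing no samples, matching the sampling structure of the
#'   observed statistic (the two treatment groups are disjoint; overlapping
#'   subsets share sampling noise and would inflate the null correlations);
#'   `"all"` uses every pair.
#' @param cor_method Correlation between connectivity vectors:
#'   `"spearman"` (default; soft-thresholded connectivities are heavy-tailed,
#'   so rank correlation weighs every member gene rather than the few hubs)
#'   or `"pearson"`.
#' @param kme_mode `"eigengene"` (default) or `"ktotal"` reading of kME.
#' @param z_threshold Disruption cutoff on Z_cor_kIM (default -2).
#' @return Tibble with the disruption-table schema: module, size,
#'   mod.cor.kIM, mean.boot.cor.kIM, sd.boot.cor.kIM, Z_cor.kIM, the four
#'   kME analogues, and `disrupted`.
#' @export
disruption_z <- function(m, ann, group_a = "CIE Drinking",
                         group_b = "Air NonDrinking", assign,
                         cfg = network_config(), n_boot = 200, seed = 1,
                         max_pairs = 2000,
                         null_stat = c("pairwise", "network_mean"),
                         pair_mode = c("disjoint", "all"),
                         kme_mode = c("eigengene", "ktotal"),
                         cor_method = c("spearman", "pearson"),
                         z_threshold = -2) {
  null_stat <- match.arg(null_stat)
  pair_mode <- match.arg(pair_mode)
  cor_method <- match.arg(cor_method)
  kme_mode <- match.arg(kme_mode)
  if (n_boot < 2) stop_cfg("n_boot must be >= 2")
  check_expression_matrix(m)
  ann <- check_ann(m, ann)
  grp <- sample_groups(ann)
  ia <- which(grp == group_a); ib <- which(grp == group_b)
  if (length(ia) < 4 || length(ib) < 4) stop_cfg("both groups need >= 4 samples")
  assign <- assign[intersect(names(assign), rownames(m))]
  mods <- setdiff(unique(assign), "grey")
  sizes <- vapply(mods, function(md) sum(assign == md), integer(1))
  small <- mods[sizes < 3]
  if (length(small)) {
    warning(sprintf("module(s) with < 3 genes have undefined correlations: %s",
                    paste(small, collapse = ", ")))
  }

  con_a <- subset_connectivity(m, ia, assign, cfg, kme_mode)
  con_b <- subset_connectivity(m, ib, assign, cfg, kme_mode)
  boot_size <- min(length(ia), length(ib))

  withr::with_seed(as.integer(seed), {
    subs <- lapply(seq_len(n_boot), function(i) sample.int(ncol(m), boot_size))
    boots <- lapply(subs, function(s) subset_connectivity(m, s, assign, cfg, kme_mode))
    inc <- vapply(subs, function(s) {
      v <- logical(ncol(m)); v[s] <- TRUE; v
    }, logical(ncol(m)))
    overlap <- crossprod(inc)
    ut <- which(upper.tri(overlap), arr.ind = TRUE)
    ovv <- overlap[ut]
    if (pair_mode == "disjoint") {
      sel <- ut[ovv == 0, , drop = FALSE]
      if (nrow(sel) < 50) {
        # too few fully disjoint pairs: take the least-overlapping ones
        sel <- ut[order(ovv)[seq_len(min(nrow(ut), 50))], , drop = FALSE]
      }
    } else {
      sel <- ut
    }
    if (null_stat == "pairwise" && nrow(sel) > max_pairs) {
      sel <- sel[sample.int(nrow(sel), max_pairs), , drop = FALSE]
    }
    pair_idx <- t(unname(sel))
    rows <- lapply(mods, function(mod) {
      sz <- sizes[[mod]]
      if (sz < 3) {
        return(tibble::tibble(
          module = mod, size = sz,
          mod.cor.kIM = NA_real_, mean.boot.cor.kIM = NA_real_,
          sd.boot.cor.kIM = NA_real_, Z_cor.kIM = NA_real_,
          mod.cor.kME = NA_real_, mean.boot.cor.kME = NA_real_,
          sd.boot.cor.kME = NA_real_, Z_cor.kME = NA_real_,
          disrupted = NA
        ))
      }
      stat_one <- function(field) {
        obs <- safe_cor(con_a[[field]][[mod]], con_b[[field]][[mod]], cor_method)
        bv <- vapply(boots, function(b) b[[field]][[mod]], numeric(sz))
        pc <- safe_cor_cols(bv, pair_idx, cor_method)
        if (null_stat == "network_mean") {
          per_net <- vapply(seq_len(n_boot), function(i) {
            mean(pc[pair_idx[1, ] == i | pair_idx[2, ] == i])
          }, numeric(1))
          mu <- mean(per_net); sdv <- sd(per_net)
        } else {
          mu <- mean(pc); sdv <- sd(pc)
        }
        c(obs = obs, mu = mu, sdv = sdv, z = (obs - mu) / sdv)
      }
      kim <- stat_one("kIM")
      kme <- stat_one("kME")
      tibble::tibble(
        module = mod, size = sz,
        mod.cor.kIM = kim[["obs"]], mean.boot.cor.kIM = kim[["mu"]],
        sd.boot.cor.kIM = kim[["sdv"]], Z_cor.kIM = kim[["z"]],
        mod.cor.kME = kme[["obs"]], mean.boot.cor.kME = kme[["mu"]],
        sd.boot.cor.kME = kme[["sdv"]], Z_cor.kME = kme[["z"]],
        disrupted = kim[["z"]] <= z_threshold
      )
    })
    dplyr::bind_rows(rows)
  })
}

safe_cor <- function(x, y, method = "spearman") {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = method)
}

safe_cor_cols <- function(mat, pair_idx, method = "spearman") {
  cc <- suppressWarnings(cor(mat, method = method))
  cc[pair_idx[1, ] + (pair_idx[2, ] - 1) * ncol(mat)]
}
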