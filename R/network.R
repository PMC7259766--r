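#' Network construction parameters
#'
#' @param power Soft-thresholding exponent beta (>= 1).
#' @param sign `"unsigned"` (default): `a_ij = |cor|^beta`; `"signed"`:
#'   `a_ij = ((1 + cor)/2)^beta`.
#' @param deep_split Branch-split sensitivity preset, 0-3 (higher = more,
#'   smaller modules).
#' @param min_module_size Smallest cluster kept as a module (default 30);
#'   smaller clusters are assigned to "grey".
#' @param merge_height Optional eigengene-dissimilarity height below which
#'   modules are merged; `NULL` (default) disables merging.
#' @return A `cie_network_config` list.
#' @export
network_config <- function(power = 6, sign = c("unsigned", "signed"),
                           deep_split = 2, min_module_size = 30,
                           merge_height = NULL) {
  sign <- match.arg(sign)
  if (power < 1) stop_cfg("power must be >= 1")
  if (!deep_split %in% 0:3) stop_cfg("deep_split must be one of 0, 1, 2, 3")
  structure(list(power = power, sign = sign, deep_split = as.integer(deep_split),
                 min_module_size = as.integer(min_module_size),
                 merge_height = merge_height),
            class = "cie_network_config")
}

#' Soft-thresholded coexpression adjacency
#'
#' Unsigned: `a_ij = |cor(x_i, x_j)|^beta`; signed: `((1 + cor)/2)^beta`.
#' The diagonal is set to 1. Zero-variance genes are excluded with a warning.
#'
#' @param m Probesets x samples matrix (>= 4 samples).
#' @param cfg A [network_config()].
#' @return Symmetric adjacency matrix in `[0, 1]` over the retained genes.
#' @export
adjacency <- function(m, cfg = network_config()) {
  check_expression_matrix(m)
  if (ncol(m) < 4) stop_cfg("adjacency needs >= 4 samples")
  v <- apply(m, 1, var)
  if (any(v <= 0)) {
    warning(sprintf("excluding %d zero-variance gene(s)", sum(v <= 0)))
    m <- m[v > 0, , drop = FALSE]
  }
  cr <- cor(t(m))
  a <- if (cfg$sign == "unsigned") abs(cr)^cfg$power else ((1 + cr) / 2)^cfg$power
  a[a > 1] <- 1
  diag(a) <- 1
  a
}

#' Scale-free topology fit of a connectivity vector
#'
#' Bins the connectivities, regresses log10 frequency on log10 mean
#' connectivity, and returns the signed fit `R^2 = -sign(slope) * R^2`
#' together with the slope and mean connectivity.
#'
#' @param k Non-negative connectivity vector.
#' @param n_bins Number of bins (default 10).
#' @return List with `r_squared` (signed), `slope`, `mean_k`; `r_squared` is
#'   `NA` when fewer than 2 bins are occupied.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 2) return(list(r_squared = NA_real_, slope = NA_real_, mean_k = mean(k)))
  brk <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k_bin <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & mean_k_bin > 0
  if (sum(keep) < 2) return(list(r_squared = NA_real_, slope = NA_real_, mean_k = mean(k)))
  lx <- log10(mean_k_bin[keep])
  ly <- log10(freq[keep])
  fit <- stats::lm(ly ~ lx)
  r2 <- cor(lx, ly)^2
  slope <- stats::coef(fit)[[2]]
  list(r_squared = -sign(slope) * r2, slope = slope, mean_k = mean(k))
}

#' Choose a soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the adjacency is built, connectivities are
#' binned, and the signed scale-free fit R^2 is computed; the chosen power is
#' the smallest whose signed R^2 reaches `r_squared_cut`. An explicit
#' `override` (the usual way to fix the power a study prescribes) is honored
#' regardless of fit.
#'
#' @param m Probesets x samples matrix.
#' @param candidate_powers Integer powers to scan (default 1:20).
#' @param r_squared_cut Signed R^2 threshold (default 0.80).
#' @param override If non-`NULL`, returned as the chosen power.
#' @param sign Network sign passed to [adjacency()].
#' @return List with `power` and `fit_table` (power, r_squared, slope, mean_k).
#' @export
pick_soft_threshold <- function(m, candidate_powers = 1:20,
                                r_squared_cut = 0.80, override = NULL,
                                sign = "unsigned") {
  fits <- lapply(candidate_powers, function(b) {
    a <- adjacency(m, network_config(power = b, sign = sign))
    k <- rowSums(a) - 1
    f <- scale_free_fit(k)
    tibble::tibble(power = b, r_squared = f$r_squared, slope = f$slope,
                   mean_k = f$mean_k)
  })
  fit_table <- dplyr::bind_rows(fits)
  if (!is.null(override)) {
    return(list(power = override, fit_table = fit_table))
  }
  ok <- which(!is.na(fit_table$r_squared) & fit_table$r_squared >= r_squared_cut)
  power <- if (length(ok)) fit_table$power[min(ok)] else
    fit_table$power[which.max(fit_table$r_squared)]
  list(power = power, fit_table = fit_table)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`, with
#' `L_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i = sum_u a_iu` over
#' `u != i`; the diagonal is 1. Shared-neighbor structure is folded into the
#' pairwise similarity, and `1 - TOM` is the clustering dissimilarity.
#'
#' @param a Adjacency matrix from [adjacency()].
#' @return TOM matrix of the same shape, entries in `[0, 1]`.
#' @export
topological_overlap <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-12)) stop_cfg("adjacency must be symmetric")
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a                       # includes no i/j self terms since diag 0
  num <- l + a
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

# deep-split presets: quantile of dendrogram merge heights at which the tree
# is cut (lower cut = finer split), documented as our native tree-cut variant
deep_split_quantile <- function(deep_split) {
  c(`0` = 0.99, `1` = 0.96, `2` = 0.92, `3` = 0.85)[[as.character(deep_split)]]
}

#' Detect coexpression modules from a TOM
#'
#' Native adaptive tree-cut: average-linkage hierarchical clustering of
#' `1 - TOM` is cut at a deep-split-indexed quantile of the merge heights
#' (the cut adapts to the dendrogram's height distribution rather than to a
#' fixed dissimilarity; higher deep-split values cut lower, yielding more
#' and smaller candidate branches). Each candidate branch of at least
#' `min_module_size` genes is then refined to its coherent core by
#' iteratively dropping genes whose mean topological overlap with the core
#' falls below half the core median (background genes chained onto a branch
#' by average linkage score well below genuine members), and finally every
#' gene is assigned to the best-scoring core it qualifies for. Genes
#' qualifying for no core are "grey". Modules are labeled through the
#' standard color sequence in order of descending size.
#'
#' @param tom TOM matrix.
#' @param cfg A [network_config()].
#' @return Named character vector: probeset -> module color ("grey" =
#'   unassigned).
#' @export
detect_modules <- function(tom, cfg = network_config()) {
  diss <- 1 - tom
  hc <- hclust(as.dist(diss), method = "average")
  q <- deep_split_quantile(cfg$deep_split)
  h_cut <- as.numeric(quantile(hc$height, q, type = 7))
  cl <- cutree(hc, h = h_cut)
  n <- nrow(tom)
  tom0 <- tom
  diag(tom0) <- 0

  core_score <- function(core) colSums(tom0[core, , drop = FALSE]) / length(core)

  # stage 1: prune each candidate branch to its coherent core (genes chained
  # onto a branch by average linkage score well below genuine members)
  sizes <- table(cl)
  seeds <- as.integer(names(sizes)[sizes >= cfg$min_module_size])
  cores <- list()
  for (s in seeds) {
    core <- which(cl == s)
    for (it in 1:4) {
      sc <- core_score(core)[core]
      new_core <- core[sc >= 0.5 * median(sc)]
      done <- length(new_core) == length(core) ||
        length(new_core) < cfg$min_module_size
      core <- new_core
      if (done) break
    }
    if (length(core) < cfg$min_module_size) next
    # coherence filter: a genuine module is far better connected within
    # than to the rest of the network; incoherent (noise) cores are not
    sc_all <- core_score(core)
    if (median(sc_all[core]) < 3 * median(sc_all[-core])) next
    cores[[length(cores) + 1]] <- core
  }

  # stage 2: re-merge cores that are fragments of one module (cross-core
  # overlap comparable to within-core overlap)
  cores <- merge_cores(tom0, cores)

  # stage 3: assign every gene to the best-scoring core it qualifies for;
  # qualification is laxer than core pruning so weakly-loaded genuine
  # members re-enter here
  labels <- rep(0L, n)
  if (length(cores)) {
    thresholds <- vapply(cores, function(core) {
      0.25 * median(core_score(core)[core])
    }, numeric(1))
    score_mat <- vapply(cores, core_score, numeric(n))
    best <- max.col(score_mat, ties.method = "first")
    best_sc <- score_mat[cbind(seq_len(n), best)]
    qualifies <- best_sc >= thresholds[best]
    labels[qualifies] <- best[qualifies]
  }
  assign_module_colors(labels, rownames(tom), cfg$min_module_size)
}

# iteratively merge core pairs whose mean cross-TOM reaches 40% of the
# smaller within-core mean TOM
merge_cores <- function(tom0, cores, ratio = 0.4) {
  repeat {
    if (length(cores) < 2) return(cores)
    within <- vapply(cores, function(core) {
      sub <- tom0[core, core]
      sum(sub) / (length(core) * (length(core) - 1))
    }, numeric(1))
    merged <- FALSE
    for (i in seq_len(length(cores) - 1)) {
      for (j in seq(i + 1, length(cores))) {
        cross <- mean(tom0[cores[[i]], cores[[j]]])
        if (cross >= ratio * min(within[i], within[j])) {
          cores[[i]] <- sort(c(cores[[i]], cores[[j]]))
          cores[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(cores)
  }
}

assign_module_colors <- function(cl, ids, min_module_size) {
  sizes <- table(cl[cl != 0])
  keep <- names(sizes)[sizes >= min_module_size]
  out <- rep("grey", length(cl))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    cols <- module_color_sequence()
    labels <- if (length(keep) <= length(cols)) cols[seq_along(keep)] else
      c(cols, paste0("module", seq_len(length(keep) - length(cols))))
    for (i in seq_along(keep)) out[cl == as.integer(keep[i])] <- labels[i]
  } else {
    warning("no cluster reached min_module_size; all genes grey")
  }
  names(out) <- ids
  out
}

#' Module eigengenes
#'
#' Per module, the first principal component of the gene-standardized member
#' submatrix (scores across samples), sign-oriented to correlate positively
#' with the module's mean standardized expression profile. Eigengenes have
#' zero mean across samples. "grey" is excluded. A size-1 module's eigengene
#' is that gene's standardized profile (logged via message).
#'
#' @param m Probesets x samples matrix covering all assigned probesets.
#' @param assign Named module assignment from [detect_modules()].
#' @return Modules x samples matrix of eigengene values.
#' @export
module_eigengenes <- function(m, assign) {
  check_expression_matrix(m)
  mods <- setdiff(unique(assign), "grey")
  if (length(mods) == 0) stop_cfg("assignment contains no non-grey module")
  miss <- setdiff(names(assign), rownames(m))
  if (length(miss)) stop_cfg("expression matrix lacks %d assigned probeset(s)", length(miss))
  eig <- matrix(NA_real_, length(mods), ncol(m),
                dimnames = list(mods, colnames(m)))
  for (mod in mods) {
    genes <- names(assign)[assign == mod]
    xs <- t(scale(t(m[genes, , drop = FALSE])))
    if (length(genes) == 1) {
      message(sprintf("module '%s' has a single gene; eigengene = its standardized profile", mod))
      e <- as.numeric(xs)
    } else {
      sv <- svd(xs, nu = 0, nv = 1)
      e <- sv$v[, 1]
    }
    avg <- colMeans(xs)
    if (cor(e, avg) < 0) e <- -e
    eig[mod, ] <- e
  }
  eig
}

#' Connectivity statistics per gene
#'
#' `kTotal` = adjacency row sum minus self; `kIM` = summed adjacency to
#' same-module genes; `kME` = correlation of the gene's profile with its
#' module eigengene (grey genes keep `kTotal` but have `NA` kIM/kME).
#'
#' @param a Adjacency matrix.
#' @param assign Module assignment over the same probesets.
#' @param eig Eigengene matrix from [module_eigengenes()].
#' @param m Expression matrix (needed for kME).
#' @return Tibble: probeset, module, kTotal, kIM, kME.
#' @export
connectivity_stats <- function(a, assign, eig, m) {
  ids <- rownames(a)
  assign <- assign[ids]
  ktotal <- rowSums(a) - 1
  kim <- rep(NA_real_, length(ids))
  kme <- rep(NA_real_, length(ids))
  for (mod in setdiff(unique(assign), "grey")) {
    sel <- which(assign == mod)
    kim[sel] <- rowSums(a[sel, sel, drop = FALSE]) - 1
    kme[sel] <- as.numeric(cor(t(m[ids[sel], , drop = FALSE]), eig[mod, ]))
  }
  tibble::tibble(probeset = ids, module = unname(assign),
                 kTotal = as.numeric(ktotal), kIM = kim, kME = kme)
}
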