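contrast_table <- function() {
  tibble::tibble(
    contrast = paste0("C", 1:6),
    group_a = c("CIE Drinking", "CIE NonDrinking", "CIE Drinking",
                "CIE Drinking", "CIE NonDrinking", "Air Drinking"),
    group_b = c("Air Drinking", "Air NonDrinking", "CIE NonDrinking",
                "Air NonDrinking", "Air Drinking", "Air NonDrinking")
  )
}

contrast_groups <- function(contrast) {
  ct <- contrast_table()
  i <- match(contrast, ct$contrast)
  if (is.na(i)) stop_cfg("unknown contrast '%s'", contrast)
  c(ct$group_a[i], ct$group_b[i])
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted values in the original order, clipped at 1.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_cfg("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(p, method = "BH")
}

group_mean_stats <- function(m, groups) {
  groups <- droplevels(as.factor(groups))
  tab <- table(groups)
  ind <- stats::model.matrix(~ groups - 1)
  sums <- m %*% ind
  gm <- sweep(sums, 2, as.numeric(tab), "/")
  colnames(gm) <- levels(groups)
  rss <- rowSums(m^2) - as.numeric(gm^2 %*% as.numeric(tab))
  rss <- pmax(rss, 0)
  df <- ncol(m) - nlevels(groups)
  list(gm = gm, rss = rss, df = df, tab = tab)
}

#' The six pairwise treatment-group contrasts
#'
#' Fits one four-group linear model per probeset (residual variance pooled
#' across all groups) and tests every pairwise group difference; the six
#' contrasts are labeled C1-C6: C1 = CIE Drinking vs Air Drinking, C2 = CIE
#' NonDrinking vs Air NonDrinking, C3 = CIE Drinking vs CIE NonDrinking,
#' C4 = CIE Drinking vs Air NonDrinking, C5 = CIE NonDrinking vs Air
#' Drinking, C6 = Air Drinking vs Air NonDrinking. BH FDR is applied within
#' each contrast. Zero-variance probesets are flagged and assigned p = 1.
#'
#' @param m Probesets x samples log2 matrix.
#' @param ann Sample annotation; all four groups must have >= 2 samples.
#' @param moderate If `TRUE`, per-probeset variances are shrunk toward a
#'   common prior (empirical-Bayes moderation via [limma::squeezeVar()])
#'   before the t statistics are formed.
#' @return Long tibble: probeset, contrast, log_ratio, t, p_value, fdr,
#'   zero_variance.
#' @export
pairwise_contrasts <- function(m, ann, moderate = FALSE) {
  check_expression_matrix(m)
  ann <- check_ann(m, ann)
  groups <- sample_groups(ann)
  tab <- table(groups)
  if (any(tab < 2)) {
    stop_cfg("every treatment group needs >= 2 samples; short: %s",
             paste(names(tab)[tab < 2], collapse = ", "))
  }
  st <- group_mean_stats(m, groups)
  s2 <- st$rss / st$df
  df <- st$df
  if (moderate) {
    sq <- limma::squeezeVar(s2, df = st$df)
    s2 <- sq$var.post
    df <- st$df + sq$df.prior
  }
  zero_var <- st$rss < .Machine$double.eps * ncol(m)
  ct <- contrast_table()
  out <- lapply(seq_len(nrow(ct)), function(i) {
    ga <- ct$group_a[i]; gb <- ct$group_b[i]
    lr <- st$gm[, ga] - st$gm[, gb]
    se <- sqrt(s2 * (1 / tab[[ga]] + 1 / tab[[gb]]))
    t_stat <- ifelse(se > 0, lr / se, 0)
    p <- 2 * pt(-abs(t_stat), df)
    p[zero_var] <- 1
    t_stat[zero_var] <- 0
    tibble::tibble(
      probeset = rownames(m), contrast = ct$contrast[i],
      log_ratio = as.numeric(lr), t = as.numeric(t_stat),
      p_value = as.numeric(p), fdr = bh_fdr(as.numeric(p)),
      zero_variance = zero_var
    )
  })
  dplyr::bind_rows(out)
}

#' Two-factor model: vapor, drinking, and their interaction
#'
#' Per probeset, fits the 2x2 fixed-effects model on sum-to-zero (balanced)
#' coding and reports the vapor main effect, drinking main effect, and
#' vapor-by-drinking interaction (Type III tests on the balanced-coded
#' design).
#'
#' @inheritParams pairwise_contrasts
#' @return Long tibble: probeset, contrast in {vapor, drinking, interaction},
#'   log_ratio (coefficient on the effect-coded design), t, F, p_value, fdr.
#' @export
two_factor_model <- function(m, ann, moderate = FALSE) {
  check_expression_matrix(m)
  ann <- check_ann(m, ann)
  vap <- factor(ann$vapor, levels = c("Air", "CIE"))
  drk <- factor(ann$drinking, levels = c("NonDrinking", "Drinking"))
  if (any(table(vap, drk) < 1)) stop_cfg("empty cell in the 2x2 design")
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  x <- stats::model.matrix(~ vap * drk)
  n <- ncol(m)
  df <- n - ncol(x)
  xtx_inv <- solve(crossprod(x))
  beta <- m %*% x %*% xtx_inv            # genes x 4 coefficients
  fit <- beta %*% t(x)
  rss <- rowSums((m - fit)^2)
  s2 <- rss / df
  if (moderate) {
    sq <- limma::squeezeVar(s2, df = df)
    s2 <- sq$var.post
    df <- df + sq$df.prior
  }
  zero_var <- rss < .Machine$double.eps * n
  terms <- c(vapor = 2L, drinking = 3L, interaction = 4L)
  out <- lapply(names(terms), function(tm) {
    j <- terms[[tm]]
    se <- sqrt(s2 * xtx_inv[j, j])
    t_stat <- ifelse(se > 0, beta[, j] / se, 0)
    p <- 2 * pt(-abs(t_stat), df)
    p[zero_var] <- 1
    t_stat[zero_var] <- 0
    tibble::tibble(
      probeset = rownames(m), contrast = tm,
      log_ratio = as.numeric(beta[, j]), t = as.numeric(t_stat),
      F = as.numeric(t_stat)^2, p_value = as.numeric(p),
      fdr = bh_fdr(as.numeric(p)), zero_variance = zero_var
    )
  })
  dplyr::bind_rows(out)
}

#' Significant-set overlaps between contrasts
#'
#' Computes the cardinality of every 2- and 3-way intersection of the
#' per-contrast significant probeset sets, the counts behind overlap Venn
#' diagrams of differentially expressed genes.
#'
#' @param results Output of [pairwise_contrasts()].
#' @param fdr Significance cutoff on the per-contrast FDR (default 0.01).
#' @return Tibble: contrasts (e.g. "C1&C4"), order (2 or 3), n_overlap.
#' @export
contrast_overlap <- function(results, fdr = 0.01) {
  sets <- split(results$probeset[results$fdr <= fdr],
                results$contrast[results$fdr <= fdr])
  labs <- sort(unique(results$contrast))
  sets <- lapply(setNames(labs, labs), function(l) sets[[l]] %||% character(0))
  if (length(labs) < 2) stop_cfg("need >= 2 contrast result sets")
  rows <- list()
  for (k in 2:min(3, length(labs))) {
    for (comb in utils::combn(labs, k, simplify = FALSE)) {
      n_ov <- length(Reduce(intersect, sets[comb]))
      rows[[length(rows) + 1]] <- tibble::tibble(
        contrasts = paste(comb, collapse = "&"), order = k, n_overlap = n_ov
      )
    }
  }
  dplyr::bind_rows(rows)
}
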