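#' Spearman correlation with t-approximation p-value
#'
#' Average ranks for ties; `t = rho * sqrt((n - 2) / (1 - rho^2))` with
#' `n - 2` degrees of freedom. For `n <= 10` an exact permutation p-value
#' can be requested.
#'
#' @param x,y Numeric vectors of equal length.
#' @param exact Use exact permutation p (only for n <= 10).
#' @return List with `rho`, `p`, `n`; `rho` is `NA` (flagged) for constant
#'   input.
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (exact && n <= 10) {
    perms <- combinat_permutations(n)
    obs <- abs(rho)
    cnt <- sum(apply(perms, 1, function(pm) abs(cor(rx, ry[pm])) >= obs - 1e-12))
    return(list(rho = rho, p = cnt / nrow(perms), n = n))
  }
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(t_stat), n - 2), n = n)
}

combinat_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- combinat_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(sub + (sub >= i), i))
  }
  out
}

trait_vector <- function(traits, trait_col, sample_map, include_nondrinkers) {
  tv <- traits[[trait_col]][match(sample_map$mouse_id, traits$mouse_id)]
  keep <- rep(TRUE, length(tv))
  if (!include_nondrinkers && "drinking" %in% names(sample_map)) {
    keep <- sample_map$drinking == "Drinking"
  }
  list(values = tv, keep = keep)
}

#' Correlate module eigengenes with drinking traits
#'
#' Spearman rank correlation of each module eigengene against each derived
#' drinking trait across samples. By default all samples enter, NonDrinking
#' animals carrying trait value 0 (only at the full-sample n do the strong
#' module-trait p-values arise); exclusion of NonDrinking samples is
#' available.
#'
#' @param eig Modules x samples eigengene matrix.
#' @param traits Output of [derive_traits()].
#' @param sample_map Tibble mapping sample_id to mouse_id (and optionally
#'   drinking status, required for `include_nondrinkers = FALSE`).
#' @param trait_cols Trait columns to use (default: b1-b6, t1-t4 and the
#'   four absolute and percent changes).
#' @param include_nondrinkers Keep NonDrinking samples (default TRUE).
#' @return Tibble: unit, trait, rho, p_value, n.
#' @export
correlate_eigengenes <- function(eig, traits, sample_map,
                                 trait_cols = default_trait_cols(),
                                 include_nondrinkers = TRUE) {
  sample_map <- sample_map[match(colnames(eig), sample_map$sample_id), ]
  if (anyNA(sample_map$mouse_id)) stop_cfg("sample_map lacks some eigengene samples")
  rows <- list()
  for (tc in trait_cols) {
    tv <- trait_vector(traits, tc, sample_map, include_nondrinkers)
    for (mod in rownames(eig)) {
      st <- spearman_test(eig[mod, tv$keep], tv$values[tv$keep])
      rows[[length(rows) + 1]] <- tibble::tibble(
        unit = mod, trait = tc, rho = st$rho, p_value = st$p, n = st$n
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Correlate individual probesets with drinking traits
#'
#' @param m Probesets x samples matrix.
#' @inheritParams correlate_eigengenes
#' @return Tibble: unit (probeset), trait, rho, p_value, n.
#' @export
correlate_genes <- function(m, traits, sample_map,
                            trait_cols = default_trait_cols(),
                            include_nondrinkers = TRUE) {
  check_expression_matrix(m)
  sample_map <- sample_map[match(colnames(m), sample_map$sample_id), ]
  if (anyNA(sample_map$mouse_id)) stop_cfg("sample_map lacks some expression samples")
  rows <- list()
  for (tc in trait_cols) {
    tv <- trait_vector(traits, tc, sample_map, include_nondrinkers)
    keep <- tv$keep & !is.na(tv$values)
    y <- tv$values[keep]
    n <- sum(keep)
    if (n < 3 || sd(y) == 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        unit = rownames(m), trait = tc, rho = NA_real_, p_value = NA_real_, n = n
      )
      next
    }
    ry <- rank(y)
    rx <- t(apply(m[, keep, drop = FALSE], 1, rank))
    rho <- as.numeric(cor(t(rx), ry))
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(t_stat), n - 2)
    p[abs(rho) >= 1] <- 0
    rows[[length(rows) + 1]] <- tibble::tibble(
      unit = rownames(m), trait = tc, rho = rho, p_value = p, n = n
    )
  }
  dplyr::bind_rows(rows)
}

default_trait_cols <- function() {
  c(paste0("b", 1:6), paste0("t", 1:4),
    paste0("abs_change_", 1:4), paste0("pct_change_", 1:4))
}
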