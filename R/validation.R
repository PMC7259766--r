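#' Permutation validation of module coherence
#'
#' For each non-grey module of size m, the observed mean off-diagonal
#' topological overlap among member pairs is compared with `n_perm` random
#' pseudo-modules of the same size drawn uniformly without replacement from
#' the whole network universe (grey genes included). The Z score
#' `(obs - null_mean) / null_sd` gives a one-sided upper-tail p (normal
#' approximation by default, empirical rank optionally), BH-adjusted across
#' modules; a module is validated at FDR <= `fdr_threshold`. The grey module
#' is reported with FDR fixed at 1.
#'
#' @param tom TOM matrix.
#' @param assign Module assignment over the same probesets.
#' @param n_perm Number of random pseudo-modules per module (default 100).
#' @param seed RNG seed.
#' @param fdr_threshold Validation cutoff (default 0.2).
#' @param p_method `"normal"` (default) or `"empirical"` rank p-values.
#' @return Tibble: module, size, obs_mean_TO, null_mean, null_sd, Z, p, fdr,
#'   validated.
#' @export
validate_modules <- function(tom, assign, n_perm = 100, seed = 1,
                             fdr_threshold = 0.2,
                             p_method = c("normal", "empirical")) {
  p_method <- match.arg(p_method)
  ids <- rownames(tom)
  if (!setequal(ids, names(assign))) {
    stop_cfg("TOM and assignment must cover the same probeset universe")
  }
  assign <- assign[ids]
  mods <- setdiff(unique(assign), "grey")
  mods <- mods[order(-table(assign)[mods])]
  n_univ <- length(ids)
  rows <- withr::with_seed(as.integer(seed), {
    lapply(mods, function(mod) {
      sel <- which(assign == mod)
      sz <- length(sel)
      if (sz < 2) {
        return(tibble::tibble(module = mod, size = sz, obs_mean_TO = NA_real_,
                              null_mean = NA_real_, null_sd = NA_real_,
                              Z = NA_real_, p = NA_real_))
      }
      obs <- mean_offdiag_tom(tom, sel)
      nulls <- vapply(seq_len(n_perm), function(i) {
        mean_offdiag_tom(tom, sample.int(n_univ, sz))
      }, numeric(1))
      mu <- mean(nulls); sdv <- sd(nulls)
      z <- (obs - mu) / sdv
      p <- if (p_method == "normal") pnorm(z, lower.tail = FALSE) else
        (1 + sum(nulls >= obs)) / (n_perm + 1)
      tibble::tibble(module = mod, size = sz, obs_mean_TO = obs,
                     null_mean = mu, null_sd = sdv, Z = z, p = p)
    })
  })
  out <- dplyr::bind_rows(rows)
  ok <- !is.na(out$p)
  out$fdr <- NA_real_
  out$fdr[ok] <- bh_fdr(out$p[ok])
  out$validated <- !is.na(out$fdr) & out$fdr <= fdr_threshold
  if ("grey" %in% assign) {
    grey_n <- sum(assign == "grey")
    out <- dplyr::bind_rows(out, tibble::tibble(
      module = "grey", size = grey_n,
      obs_mean_TO = if (grey_n >= 2) mean_offdiag_tom(tom, which(assign == "grey")) else NA_real_,
      null_mean = NA_real_, null_sd = NA_real_, Z = NA_real_, p = NA_real_,
      fdr = 1, validated = FALSE
    ))
  }
  out
}

mean_offdiag_tom <- function(tom, sel) {
  sub <- tom[sel, sel]
  (sum(sub) - length(sel)) / (length(sel) * (length(sel) - 1))
}
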