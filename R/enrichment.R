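#' Exact hypergeometric overlap test
#'
#' Upper-tail probability of observing at least `|A intersect B|` shared
#' elements when a set of size `|A|` and a set of size `|B|` are drawn from a
#' common universe of size `N`.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector defining the background.
#' @return List with `k` (overlap), `p` (upper-tail hypergeometric p),
#'   `m` (= |A|), `n` (= |B|), `N`.
#' @export
hypergeom_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  off_a <- setdiff(set_a, universe)
  off_b <- setdiff(set_b, universe)
  if (length(off_a) || length(off_b)) {
    stop_cfg("elements outside the universe: %s",
             paste(utils::head(c(off_a, off_b), 5), collapse = ", "))
  }
  k <- length(intersect(set_a, set_b))
  m <- length(set_a); n <- length(set_b); big_n <- length(universe)
  p <- phyper(k - 1, m, big_n - m, n, lower.tail = FALSE)
  list(k = k, p = p, m = m, n = n, N = big_n)
}

#' Module-by-list overlap enrichment
#'
#' Tests every non-grey module against every supplied probeset list by the
#' exact hypergeometric upper tail, corrected across the full module x list
#' table. BH at FDR <= 0.05 is the convention for module-versus-module-list
#' comparisons; Bonferroni <= 0.05 for cell-type marker lists.
#'
#' @param assign Module assignment (probeset -> module).
#' @param lists Named list of character vectors (gene/probeset lists).
#' @param universe Background probesets (default: all assigned probesets,
#'   i.e. the network input universe).
#' @param correction `"BH"` or `"bonferroni"`.
#' @param threshold Significance cutoff on the corrected p (default 0.05).
#' @return Tibble: module, list, k, module_size, list_size, universe_size,
#'   p, p_corrected, significant.
#' @export
module_list_enrichment <- function(assign, lists, universe = names(assign),
                                   correction = c("BH", "bonferroni"),
                                   threshold = 0.05) {
  correction <- match.arg(correction)
  mods <- setdiff(unique(assign), "grey")
  keep <- vapply(lists, length, integer(1)) > 0
  if (any(!keep)) {
    warning(sprintf("excluding empty list(s): %s",
                    paste(names(lists)[!keep], collapse = ", ")))
    lists <- lists[keep]
  }
  lists <- lapply(lists, intersect, y = universe)
  rows <- list()
  for (mod in mods) {
    mod_genes <- intersect(names(assign)[assign == mod], universe)
    for (ln in names(lists)) {
      hv <- hypergeom_overlap(mod_genes, lists[[ln]], universe)
      rows[[length(rows) + 1]] <- tibble::tibble(
        module = mod, list = ln, k = hv$k, module_size = hv$m,
        list_size = hv$n, universe_size = hv$N, p = hv$p
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_corrected <- if (correction == "BH") bh_fdr(out$p) else
    pmin(1, out$p * nrow(out))
  out$significant <- out$p_corrected <= threshold
  out
}
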