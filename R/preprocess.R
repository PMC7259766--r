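#' Read a log2 expression matrix from delimited text
#'
#' Expects a header row of sample IDs and a first column of probeset IDs.
#' Duplicate IDs, ragged rows, non-numeric cells and missing values are
#' rejected with an error naming the offending row or column.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, probesets x samples.
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop_cfg("expression file '%s' has no data rows", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples) > 0) {
    stop_cfg("duplicated sample ID(s): %s",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  ncol_exp <- length(header)
  body <- fields[-1]
  nf <- lengths(body)
  if (any(nf != ncol_exp)) {
    stop_cfg("ragged row(s) at line(s): %s",
             paste(which(nf != ncol_exp) + 1L, collapse = ", "))
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids) > 0) {
    stop_cfg("duplicated probeset ID(s): %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(ncol_exp - 1L))
  )
  m <- t(matrix(vals, ncol_exp - 1L, length(body)))
  dimnames(m) <- list(ids, samples)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop_cfg("non-numeric or missing cell at probeset '%s', sample '%s'",
             ids[bad[1]], samples[bad[2]])
  }
  m
}

#' Write an expression matrix as TSV
#'
#' Values are written with a fixed decimal precision (default 7 digits after
#' the decimal point, ample for log2 intensities); the round trip
#' `read_expression(write_expression(m))` reproduces values exactly as
#' formatted.
#'
#' @param m Probesets x samples numeric matrix.
#' @param path Output path.
#' @param digits Decimal digits written.
#' @export
write_expression <- function(m, path, digits = 7) {
  check_expression_matrix(m)
  header <- paste(c("probeset_id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], formatC(m[i, ], format = "f", digits = digits)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution given
#' by the row-wise mean of the sorted columns. Ties within a column receive
#' the mean of the reference values at their rank positions.
#'
#' @param m Probesets x samples numeric matrix, >= 2 samples.
#' @return Matrix of the same shape whose columns share one distribution.
#' @export
quantile_normalize <- function(m) {
  check_expression_matrix(m)
  if (ncol(m) < 2) stop_cfg("quantile normalization needs >= 2 samples")
  sorted <- apply(m, 2, sort)
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    v <- m[o, j]
    tie_grp <- cumsum(!duplicated(v))
    # each tie group gets the mean of the reference values at its rank positions
    out[o, j] <- stats::ave(ref, tie_grp)
  }
  out
}

#' Row-wise one-way ANOVA
#'
#' Vectorized one-way fixed-effects ANOVA of every probeset across treatment
#' groups (pooled within-group variance). Zero-variance probesets get
#' F = 0, p = 1.
#'
#' @param m Probesets x samples matrix.
#' @param groups Group factor, one level per treatment group.
#' @return Tibble: probeset, F, p_value, df1, df2.
#' @export
row_anova <- function(m, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- ncol(m)
  if (k < 2) stop_cfg("ANOVA needs >= 2 groups")
  tab <- table(groups)
  if (any(tab < 2)) {
    stop_cfg("group(s) with < 2 samples: %s",
             paste(names(tab)[tab < 2], collapse = ", "))
  }
  ind <- stats::model.matrix(~ groups - 1)
  gm <- m %*% ind %*% diag(1 / as.numeric(tab))  # genes x k group means
  grand <- rowMeans(m)
  ss_between <- as.numeric((gm - grand)^2 %*% as.numeric(tab))
  ss_total <- rowSums((m - grand)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  df1 <- k - 1
  df2 <- n - k
  msb <- ss_between / df1
  msw <- ss_within / df2
  f <- msb / msw
  p <- pf(f, df1, df2, lower.tail = FALSE)
  zero_var <- ss_total < .Machine$double.eps * n
  f[zero_var] <- 0
  p[zero_var] <- 1
  tibble::tibble(probeset = rownames(m), F = as.numeric(f),
                 p_value = as.numeric(p), df1 = df1, df2 = df2)
}

#' Select the network input probeset universe by one-way ANOVA
#'
#' Keeps probesets whose four-group one-way ANOVA reaches the given
#' Benjamini-Hochberg FDR, the selection rule used to restrict network
#' construction to treatment-responsive probesets.
#'
#' @param m Probesets x samples log2 matrix.
#' @param ann Sample annotation (sample_id, vapor, drinking).
#' @param fdr_threshold BH FDR cutoff (default 0.01).
#' @return Character vector of retained probeset IDs, in matrix order.
#' @export
anova_filter <- function(m, ann, fdr_threshold = 0.01) {
  check_expression_matrix(m)
  ann <- check_ann(m, ann)
  res <- row_anova(m, sample_groups(ann))
  fdr <- bh_fdr(res$p_value)
  res$probeset[fdr <= fdr_threshold]
}

#' Union of per-region probeset selections
#'
#' A probeset significant in any region enters the shared network universe.
#' Order of the first appearance is preserved (matrix order when the inputs
#' are in matrix order).
#'
#' @param sets List of character vectors of probeset IDs.
#' @return Character vector, the set union.
#' @export
union_filter <- function(sets) {
  stopifnot(is.list(sets))
  unique(unlist(sets, use.names = FALSE))
}
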