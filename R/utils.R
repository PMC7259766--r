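#' @importFrom stats cor pf pt pnorm phyper p.adjust sd quantile rnorm runif
#' @importFrom stats hclust cutree as.dist setNames var median complete.cases
#' @importFrom utils head
#' @importFrom rlang .data
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive a stage-specific seed from a master seed
#'
#' All resampling stages draw their randomness from a single master seed via a
#' fixed per-stage offset, so a pipeline run is reproducible end to end while
#' stages remain independently re-runnable.
#'
#' @param seed Master integer seed.
#' @param stage Stage name (character).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  offsets <- c(
    drinking = 11L, expression = 23L, traits = 31L, network = 41L,
    validation = 53L, correlation = 61L, disruption = 71L,
    enrichment = 83L, pipeline = 97L
  )
  if (!stage %in% names(offsets)) stop_cfg("unknown stage '%s'", stage)
  as.integer((as.numeric(seed) * 131L + offsets[[stage]]) %% 2147483647)
}

# standard module color sequence, assigned by descending module size
module_color_sequence <- function() {
  c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3",
    "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3"
  )
}

group_levels <- function() {
  c("CIE Drinking", "Air Drinking", "CIE NonDrinking", "Air NonDrinking")
}

#' Treatment group labels from a sample annotation
#'
#' @param ann Sample annotation with `vapor` and `drinking` columns.
#' @return Factor of group labels ("CIE Drinking", ..., "Air NonDrinking").
#' @export
sample_groups <- function(ann) {
  g <- paste(ann$vapor, ann$drinking)
  bad <- setdiff(unique(g), group_levels())
  if (length(bad) > 0) {
    stop_cfg("unknown treatment group(s): %s", paste(bad, collapse = ", "))
  }
  factor(g, levels = group_levels())
}

check_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop_cfg("expression must be a numeric matrix")
  if (anyNA(m)) stop_cfg("expression matrix contains missing values (unsupported)")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)) > 0) {
    stop_cfg("expression matrix must have unique probeset rownames")
  }
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)) > 0) {
    stop_cfg("expression matrix must have unique sample colnames")
  }
  invisible(m)
}

check_ann <- function(m, ann) {
  need <- c("sample_id", "vapor", "drinking")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) stop_cfg("annotation lacks column(s): %s", paste(miss, collapse = ", "))
  if (!setequal(colnames(m), ann$sample_id)) {
    stop_cfg("annotation samples do not match expression matrix columns")
  }
  ann[match(colnames(m), ann$sample_id), , drop = FALSE]
}
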