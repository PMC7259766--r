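#' Derive drinking traits from daily intake records
#'
#' Weekly baseline means b1-b6 and per-CIE-cycle means t1-t4 are arithmetic
#' means of the five daily intakes of each phase. Absolute change for cycle c
#' is `t_c - baseline`; percent change is `100 * (t_c - baseline) /
#' baseline`, flagged `NA` when the baseline reference is zero (NonDrinking
#' animals, which carry all-zero traits so trait vectors span every sample).
#'
#' @param rec Drinking record tibble (mouse_id, session, phase, intake_gkg;
#'   a `drinking` column, if present, marks NonDrinking animals).
#' @param baseline Baseline reference: `"mean"` (mean of the six weekly
#'   baseline means, default) or `"lastweek"` (week-6 mean only).
#' @return Tibble keyed by mouse_id with b1..b6, t1..t4, baseline_ref,
#'   abs_change_1..4, pct_change_1..4.
#' @export
derive_traits <- function(rec, baseline = c("mean", "lastweek")) {
  baseline <- match.arg(baseline)
  need <- c("mouse_id", "session", "phase", "intake_gkg")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop_cfg("drinking record lacks column(s): %s", paste(miss, collapse = ", "))
  phases <- c(paste0("baseline", 1:6), paste0("cie", 1:4))
  bad <- setdiff(unique(rec$phase), phases)
  if (length(bad)) stop_cfg("unknown phase label(s): %s", paste(bad, collapse = ", "))

  wide <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(rec, .data$mouse_id, .data$phase),
                     mean_intake = mean(.data$intake_gkg), n_sess = dplyr::n(),
                     .groups = "drop"),
    id_cols = "mouse_id", names_from = "phase", values_from = "mean_intake"
  )
  miss_ph <- setdiff(phases, names(wide))
  if (length(miss_ph)) {
    stop_cfg("phase(s) with no sessions: %s", paste(miss_ph, collapse = ", "))
  }
  if (anyNA(wide[phases])) {
    bad_mouse <- wide$mouse_id[!complete.cases(wide[phases])]
    stop_cfg("mouse/mice with a phase lacking sessions: %s",
             paste(bad_mouse, collapse = ", "))
  }

  b <- unname(as.matrix(wide[paste0("baseline", 1:6)]))
  t_ <- unname(as.matrix(wide[paste0("cie", 1:4)]))
  base_ref <- if (baseline == "mean") rowMeans(b) else b[, 6]
  out <- tibble::tibble(mouse_id = wide$mouse_id)
  for (w in 1:6) out[[paste0("b", w)]] <- b[, w]
  for (cc in 1:4) out[[paste0("t", cc)]] <- t_[, cc]
  out$baseline_ref <- base_ref
  for (cc in 1:4) {
    out[[paste0("abs_change_", cc)]] <- t_[, cc] - base_ref
    out[[paste0("pct_change_", cc)]] <-
      ifelse(base_ref > 0, 100 * (t_[, cc] - base_ref) / base_ref, NA_real_)
  }
  out
}
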