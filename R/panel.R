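#' Select the longitudinal methylation panel
#'
#' Applies the composite selection rule to a CpG-wise scan: a probe enters
#' the panel when (i) its AD main-effect p-value is below `p_thresh`,
#' (ii) the absolute AD estimate is at least `effect_thresh` on the beta
#' scale, and (iii) the fitted case-control difference has the same sign at
#' the earliest and latest observed times (no crossover interaction). The
#' probe's direction sign is the sign of its AD estimate and its optional
#' weight is the AD estimate itself (used by the weighted panel variant).
#' Benjamini-Hochberg q-values are carried along for reporting; the
#' p/effect thresholds are the exploratory criteria and are recorded in the
#' panel metadata.
#'
#' @param results scan table from [ewas_scan()] (needs `estimate`, `p`,
#'   `diff_at_tmin`, `diff_at_tmax`).
#' @param p_thresh AD-term p-value threshold (default 0.001).
#' @param effect_thresh minimum |AD estimate| in beta units (default 0.05).
#'
#' @return An object of class `panel_definition`: data.frame with
#'   `probe_id`, `sign` (+/-1), `weight`, plus `p_thresh`/`effect_thresh`
#'   attributes. An empty selection is returned (with a warning) as an
#'   empty panel.
#' @export
select_panel <- function(results, p_thresh = 0.001, effect_thresh = 0.05) {
  need <- c("probe_id", "estimate", "p", "diff_at_tmin", "diff_at_tmax")
  if (!all(need %in% names(results))) {
    stop_mp("scan results must include ", paste(need, collapse = ", "))
  }
  ok <- !is.na(results$p) & !is.na(results$estimate)
  keep <- ok & results$p < p_thresh &
    abs(results$estimate) >= effect_thresh &
    results$diff_at_tmin * results$diff_at_tmax > 0
  sel <- results[keep, , drop = FALSE]
  if (nrow(sel) == 0) {
    warning("no probe passed the selection criteria; returning an empty ",
            "panel", call. = FALSE)
  }
  panel <- data.frame(probe_id = sel$probe_id,
                      sign = ifelse(sel$estimate >= 0, 1, -1),
                      weight = sel$estimate,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(panel, class = c("panel_definition", "data.frame"),
            p_thresh = p_thresh, effect_thresh = effect_thresh)
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf("Methylation panel: %d CpGs (%d hyper-, %d hypomethylated in cases); p < %g, |effect| >= %g\n",
              nrow(x), sum(x$sign > 0), sum(x$sign < 0),
              attr(x, "p_thresh"), attr(x, "effect_thresh")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Signed-sum panel score
#'
#' The composite biomarker: each panel CpG's beta value is multiplied by
#' +1 or -1 according to its direction of association (or by its LMM effect
#' size for the weighted variant) and the products are summed per sample.
#'
#' @param m CpG x sample beta matrix containing every panel probe.
#' @param panel a [select_panel()] result (or data.frame with `probe_id`,
#'   `sign`, `weight`).
#' @param weighted use `weight` instead of `sign` as multipliers.
#'
#' @return Named numeric vector of per-sample scores.
#' @export
panel_score <- function(m, panel, weighted = FALSE) {
  assert_beta_matrix(m)
  if (nrow(panel) == 0) {
    return(stats::setNames(rep(0, ncol(m)), colnames(m)))
  }
  missing_probes <- setdiff(panel$probe_id, rownames(m))
  if (length(missing_probes)) {
    stop_mp("panel probe(s) absent from the matrix: ",
            paste(utils::head(missing_probes, 10), collapse = ", "))
  }
  w <- if (weighted) panel$weight else panel$sign
  score <- drop(crossprod(m[panel$probe_id, , drop = FALSE], w))
  stats::setNames(as.numeric(score), colnames(m))
}
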