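# Plain-text readers and writers for the pipeline's interchange formats:
# gzipped TSV beta matrices, CSV sample sheets / blacklists / panels /
# proportions, clock coefficient CSVs with a JSON sidecar, sPLS-DA models
# and ground truth as JSON.

#' Write / read a beta matrix as gzipped TSV
#'
#' Rows are CpG probe IDs (first column `probe_id`), columns sample IDs.
#'
#' @param m CpG x sample beta matrix.
#' @param path output path (".tsv.gz" conventional).
#' @return `read_beta_matrix` returns the numeric matrix.
#' @export
write_beta_matrix <- function(m, path) {
  assert_beta_matrix(m)
  con <- gzfile(path, "w")
  on.exit(close(con))
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(gzfile(path), check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  m
}

#' Write / read a sample sheet as CSV
#'
#' @param sheet sample sheet data.frame.
#' @param path CSV path.
#' @return `read_sample_sheet` returns the data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a probe blacklist (one probe per line, header `probe_id`)
#'
#' @param path CSV path.
#' @return Character vector of probe IDs.
#' @export
read_blacklist <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"probe_id" %in% names(df)) {
    stop_mp("blacklist file must have a 'probe_id' header column")
  }
  df$probe_id
}

#' Write / read a clock definition (coefficient CSV + JSON sidecar)
#'
#' The CSV holds `(probe_id, weight)`; the sidecar (same path with
#' ".json" appended) holds name, intercept, calibration, adult_age and the
#' age-estimator flag. Published coefficient tables in this schema are
#' accepted verbatim.
#'
#' @param clock a [clock_definition()].
#' @param path CSV path.
#' @return `read_clock` returns the [clock_definition()].
#' @export
write_clock <- function(clock, path) {
  utils::write.csv(data.frame(probe_id = names(clock$weights),
                              weight = unname(clock$weights)),
                   path, row.names = FALSE)
  meta <- clock[c("name", "intercept", "calibration", "adult_age",
                  "is_age_estimator")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  clock_definition(name = meta$name, intercept = meta$intercept,
                   weights = stats::setNames(df$weight, df$probe_id),
                   calibration = meta$calibration,
                   adult_age = meta$adult_age,
                   is_age_estimator = meta$is_age_estimator)
}

#' Write / read a panel definition as CSV
#'
#' Columns `probe_id`, `sign`, `weight`; the selection thresholds travel as
#' extra columns `p_thresh` / `effect_thresh` on the first row.
#'
#' @param panel a [select_panel()] panel.
#' @param path CSV path.
#' @return `read_panel` returns the `panel_definition`.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  df$p_thresh <- c(attr(panel, "p_thresh"), rep(NA, max(0, nrow(df) - 1)))
  df$effect_thresh <- c(attr(panel, "effect_thresh"),
                        rep(NA, max(0, nrow(df) - 1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df[, c("probe_id", "sign", "weight")],
            class = c("panel_definition", "data.frame"),
            p_thresh = df$p_thresh[1], effect_thresh = df$effect_thresh[1])
}

#' Write estimated cell proportions as CSV
#'
#' @param props table from [estimate_proportions()].
#' @param path CSV path.
#' @export
write_proportions <- function(props, path) {
  utils::write.csv(props, path, row.names = FALSE)
  invisible(path)
}

#' Write a scan result table as TSV
#'
#' @param results table from [ewas_scan()].
#' @param path TSV path.
#' @export
write_scan_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read an sPLS-DA model as JSON
#'
#' Loadings are stored as probe-to-weight maps per component, together with
#' the deflation loadings, Y-coefficients, centring/scaling vectors, class
#' centroids and levels needed to score and classify new samples.
#'
#' @param model an [splsda_fit()] model.
#' @param path JSON path.
#' @return `read_splsda` returns the `splsda` model.
#' @export
write_splsda <- function(model, path) {
  loadings <- lapply(seq_len(model$ncomp), function(h) {
    w <- model$W[, h]
    as.list(w[w != 0])
  })
  obj <- list(loadings = loadings,
              features = rownames(model$W),
              W = unclass(unname(model$W)), P = unclass(unname(model$P)),
              C = unclass(unname(model$C)),
              centroids = unclass(unname(model$centroids)),
              xmean = as.list(model$xmean), xsd = as.list(model$xsd),
              ymean = as.list(model$ymean), ysd = as.list(model$ysd),
              levels = model$levels, keepX = model$keepX,
              ncomp = model$ncomp)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_splsda
#' @export
read_splsda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- obj$features
  ncomp <- obj$ncomp
  as_mat <- function(x, rn) {
    m <- matrix(as.numeric(x), nrow = length(rn))
    rownames(m) <- rn
    m
  }
  structure(list(W = as_mat(obj$W, feats), P = as_mat(obj$P, feats),
                 C = as_mat(obj$C, obj$levels), T = NULL,
                 centroids = as_mat(obj$centroids, obj$levels),
                 xmean = unlist(obj$xmean), xsd = unlist(obj$xsd),
                 ymean = unlist(obj$ymean), ysd = unlist(obj$ysd),
                 levels = obj$levels, keepX = obj$keepX, ncomp = ncomp,
                 y = NULL),
            class = "splsda")
}

#' Write cohort ground truth as JSON
#'
#' @param truth the `truth` element of [generate_cohort()].
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(cpg_id = truth$cpg_id, class = truth$class,
              true_delta_beta = truth$true_delta_beta,
              true_slope = truth$true_slope,
              onset_age = as.list(truth$onset_age),
              cell_proportions = truth$cell_proportions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
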