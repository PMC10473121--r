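#' Reference-based blood cell deconvolution
#'
#' Estimates the cell-type composition of each bulk sample by projecting
#' its beta values onto purified cell-type reference profiles under
#' non-negativity and sum-to-one constraints (Houseman-style constrained
#' projection). The quadratic program is solved by Lawson-Hanson
#' non-negative least squares with the equality constraint imposed through
#' a heavily weighted augmentation row, followed by exact renormalization;
#' on noise-free convex mixtures the composition is recovered to machine
#' precision.
#'
#' @param m CpG x sample beta matrix; rownames must share probes with the
#'   reference (at least as many shared probes as cell types).
#' @param ref CpG x cell-type reference matrix, e.g. from
#'   [generate_reference_panel()].
#'
#' @return A data.frame with `sample_id` and one proportion column per cell
#'   type; rows sum to 1 within 1e-6.
#' @export
estimate_proportions <- function(m, ref) {
  assert_beta_matrix(m)
  if (is.null(rownames(ref))) stop_mp("reference must have probe rownames")
  shared <- intersect(rownames(m), rownames(ref))
  k <- ncol(ref)
  if (length(shared) < k) {
    stop_mp("need at least ", k, " reference CpGs present in the matrix")
  }
  R <- as.matrix(ref[shared, , drop = FALSE])
  if (qr(R)$rank < k) {
    stop_mp("identifiability error: reference matrix is rank deficient")
  }
  lambda <- 1000  # weight on the sum-to-one row
  A <- rbind(R, rep(lambda, k))
  out <- matrix(NA_real_, ncol(m), k,
                dimnames = list(colnames(m), colnames(ref)))
  for (s in seq_len(ncol(m))) {
    b <- m[shared, s]
    ok <- !is.na(b)
    if (sum(ok) < k) {
      stop_mp("sample ", colnames(m)[s], " observes fewer reference CpGs ",
              "than cell types")
    }
    fit <- pracma::lsqnonneg(rbind(R[ok, , drop = FALSE], rep(lambda, k)),
                             c(b[ok], lambda))
    p <- fit$x
    tot <- sum(p)
    if (tot <= 0) stop_mp("deconvolution failed for sample ", colnames(m)[s])
    out[s, ] <- p / tot
  }
  data.frame(sample_id = colnames(m), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Granulocyte-proportion model covariate
#'
#' Extracts the granulocyte fraction per sample (the dominant blood cell
#' type, used to adjust downstream models), optionally z-scored across
#' samples.
#'
#' @param props proportions table from [estimate_proportions()].
#' @param zscore if TRUE, return the z-scored fraction (error on zero
#'   variance).
#' @param column name of the granulocyte column.
#'
#' @return Named numeric vector (by sample ID).
#' @export
granulocyte_covariate <- function(props, zscore = FALSE,
                                  column = "granulocyte") {
  if (!column %in% names(props)) {
    stop_mp("granulocyte column '", column, "' not present")
  }
  g <- stats::setNames(props[[column]], props$sample_id)
  if (zscore) g <- zscale(g)
  g
}
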