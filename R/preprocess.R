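#' Mask low-quality methylation calls by detection p-value
#'
#' Sets beta values whose detection p-value is strictly greater than the
#' threshold to missing (NA); entries at or below the threshold are left
#' untouched.
#'
#' @param m CpG x sample beta matrix.
#' @param detp matching matrix of per-entry detection p-values (same
#'   dimensions and dimnames).
#' @param threshold detection p-value cutoff (default 0.05; strict `>`).
#'
#' @return The beta matrix with failing entries set to NA; the number of
#'   newly masked entries is attached as attribute `n_masked`.
#' @export
mask_low_quality <- function(m, detp, threshold = 0.05) {
  assert_beta_matrix(m)
  if (missing(detp) || is.null(detp)) {
    stop_mp("configuration error: detection p-value matrix is required")
  }
  if (!identical(dim(m), dim(detp))) {
    stop_mp("detection p-value matrix dimensions do not match the beta matrix")
  }
  bad <- !is.na(detp) & detp > threshold
  m[bad] <- NA_real_
  attr(m, "n_masked") <- sum(bad)
  m
}

#' Remove blacklisted probes
#'
#' Drops the union of probe blacklists (e.g. multimapping, SNP-proximal,
#' meQTL, sex-chromosome probes) from a beta matrix. Blacklist IDs not
#' present in the matrix are ignored with a warning.
#'
#' @param m CpG x sample beta matrix.
#' @param blacklists named list of character vectors of probe IDs; sets may
#'   overlap.
#'
#' @return The filtered matrix; attribute `filter_report` holds per-set and
#'   total removal counts.
#' @export
filter_probes <- function(m, blacklists = list()) {
  assert_beta_matrix(m)
  if (length(blacklists) == 0) {
    attr(m, "filter_report") <- list(per_set = integer(0), n_removed = 0L,
                                     n_in = nrow(m), n_out = nrow(m))
    return(m)
  }
  all_ids <- rownames(m)
  per_set <- vapply(blacklists, function(b) sum(b %in% all_ids), integer(1))
  unknown <- setdiff(unique(unlist(blacklists)), all_ids)
  if (length(unknown)) {
    warning(length(unknown), " blacklisted probe ID(s) not present in the ",
            "matrix were ignored", call. = FALSE)
  }
  drop <- unique(unlist(blacklists))
  keep <- setdiff(all_ids, drop)
  out <- m[keep, , drop = FALSE]
  attr(out, "filter_report") <- list(per_set = per_set,
                                     n_removed = nrow(m) - nrow(out),
                                     n_in = nrow(m), n_out = nrow(out))
  out
}

#' Drop probes with any missing value
#'
#' Removes every probe row containing at least one missing entry, the
#' complete-case rule used before CpG-wise association scans.
#'
#' @param m CpG x sample beta matrix.
#'
#' @return The complete-case matrix; attribute `drop_report` holds
#'   `(n_in, n_removed, n_out)`.
#' @export
drop_incomplete_probes <- function(m) {
  assert_beta_matrix(m)
  incomplete <- rowSums(is.na(m)) > 0
  out <- m[!incomplete, , drop = FALSE]
  attr(out, "drop_report") <- list(n_in = nrow(m),
                                   n_removed = sum(incomplete),
                                   n_out = nrow(out))
  out
}

# ---- beta-mixture quantile normalization -----------------------------------

# EM fit of a 3-component beta mixture by responsibility-weighted
# method-of-moments updates; components ordered unmethylated / hemi /
# methylated by mean.
fit_beta_mixture3 <- function(x, max_iter = 100, tol = 1e-4) {
  x <- pmin(pmax(x, 1e-4), 1 - 1e-4)
  km <- stats::kmeans(x, centers = c(0.15, 0.5, 0.85), iter.max = 20)
  ord <- order(km$centers)
  resp <- matrix(0, length(x), 3)
  for (g in 1:3) resp[km$cluster == ord[g], g] <- 1

  mom <- function(m, v) {
    v <- max(v, 1e-6)
    v <- min(v, m * (1 - m) * 0.999)
    c0 <- m * (1 - m) / v - 1
    c(shape1 = max(m * c0, 1e-2), shape2 = max((1 - m) * c0, 1e-2))
  }
  pars <- matrix(0, 3, 2)
  pi_g <- colMeans(resp)
  for (g in 1:3) {
    w <- resp[, g] / sum(resp[, g])
    m <- sum(w * x); v <- sum(w * (x - m)^2)
    pars[g, ] <- mom(m, v)
  }
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(g) {
      pi_g[g] * stats::dbeta(x, pars[g, 1], pars[g, 2])
    }, numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    resp <- dens / tot
    pi_g <- colMeans(resp)
    for (g in 1:3) {
      sw <- sum(resp[, g])
      if (sw < 1e-8) next
      w <- resp[, g] / sw
      m <- sum(w * x); v <- sum(w * (x - m)^2)
      pars[g, ] <- mom(m, v)
    }
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  means <- pars[, 1] / rowSums(pars)
  ord <- order(means)
  list(shape1 = pars[ord, 1], shape2 = pars[ord, 2], pi = pi_g[ord],
       means = means[ord], converged = converged)
}

bmiq_map_sample <- function(x1, x2) {
  fit1 <- fit_beta_mixture3(x1)
  fit2 <- fit_beta_mixture3(x2)
  if (!fit1$converged || !fit2$converged) return(NULL)
  xc <- pmin(pmax(x2, 1e-4), 1 - 1e-4)
  dens <- vapply(1:3, function(g) {
    fit2$pi[g] * stats::dbeta(xc, fit2$shape1[g], fit2$shape2[g])
  }, numeric(length(xc)))
  state <- max.col(dens, ties.method = "first")
  out <- x2
  for (g in 1:3) {
    sel <- state == g
    if (!any(sel)) next
    u <- stats::pbeta(xc[sel], fit2$shape1[g], fit2$shape2[g])
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    out[sel] <- stats::qbeta(u, fit1$shape1[g], fit1$shape2[g])
  }
  clip01(out)
}

#' Beta-mixture quantile normalization of the two probe design classes
#'
#' A simplified within-sample BMIQ-style normalization: per sample, a
#' three-state (unmethylated / hemi-methylated / methylated) beta mixture is
#' fitted by EM to each probe design class, and design-class-II values are
#' quantile-mapped state-by-state onto the class-I mixture. Rank order is
#' preserved within each (design class, state) stratum; output stays in
#' \[0, 1\]. Samples for which the EM does not converge are returned
#' unchanged with a warning. Full fidelity to the original method's
#' state-assignment edge cases is not claimed.
#'
#' @param m CpG x sample beta matrix (no missing values in fitted probes;
#'   NAs are passed through untouched).
#' @param design per-probe design class, character vector of "I"/"II" named
#'   by (or ordered as) the probes of `m`.
#'
#' @return The normalized matrix (class-I probes unchanged).
#' @export
bmiq_normalize <- function(m, design) {
  assert_beta_matrix(m)
  if (missing(design) || is.null(design)) {
    stop_mp("per-probe design class (I/II) is required")
  }
  if (!is.null(names(design))) design <- design[rownames(m)]
  if (length(design) != nrow(m) || anyNA(design)) {
    stop_mp("design class must cover every probe of the matrix")
  }
  i1 <- design == "I"; i2 <- design == "II"
  if (!any(i1) || !any(i2)) return(m)  # single design class: nothing to map
  out <- m
  for (s in seq_len(ncol(m))) {
    x1 <- m[i1, s]; x2 <- m[i2, s]
    ok1 <- !is.na(x1); ok2 <- !is.na(x2)
    mapped <- tryCatch(bmiq_map_sample(x1[ok1], x2[ok2]),
                       error = function(e) NULL)
    if (is.null(mapped)) {
      warning("BMIQ EM did not converge for sample ", colnames(m)[s],
              "; returned unnormalized", call. = FALSE)
      next
    }
    v <- m[i2, s]
    v[ok2] <- mapped
    out[i2, s] <- v
  }
  out
}

#' K-nearest-neighbour imputation of missing beta values
#'
#' Each missing entry is replaced by the inverse-distance-weighted mean of
#' the k nearest samples' values at that probe, nearness measured by
#' Euclidean distance over probes observed in both samples (scaled to a
#' per-probe average so differing overlap sizes are comparable). Observed
#' entries are never altered.
#'
#' @param m CpG x sample beta matrix with NAs marking missing entries.
#' @param k number of neighbours (default 10; requires at least k+1
#'   samples).
#'
#' @return A complete matrix in \[0, 1\].
#' @export
knn_impute <- function(m, k = 10) {
  assert_beta_matrix(m)
  if (!anyNA(m)) return(m)
  if (ncol(m) < k + 1) {
    stop_mp("knn_impute requires at least k + 1 samples (k = ", k, ")")
  }
  all_missing <- rowSums(!is.na(m)) == 0
  if (any(all_missing)) {
    stop_mp("probe(s) missing in every sample: ",
            paste(utils::head(rownames(m)[all_missing], 5), collapse = ", "))
  }
  obs <- !is.na(m)
  # pairwise mean squared difference over mutually observed probes
  need <- which(colSums(!obs) > 0)
  for (s in need) {
    miss_probes <- which(!obs[, s])
    d2 <- vapply(seq_len(ncol(m)), function(t) {
      if (t == s) return(Inf)
      both <- obs[, s] & obs[, t]
      if (!any(both)) return(Inf)
      mean((m[both, s] - m[both, t])^2)
    }, numeric(1))
    for (p in miss_probes) {
      donors <- which(obs[p, ] & is.finite(d2))
      if (!length(donors)) {
        stop_mp("no donor sample observed for probe ", rownames(m)[p])
      }
      nb <- donors[order(d2[donors])][seq_len(min(k, length(donors)))]
      w <- 1 / (sqrt(d2[nb]) + 1e-12)
      m[p, s] <- sum(w * m[p, nb]) / sum(w)
    }
  }
  m
}
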