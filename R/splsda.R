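# Sparse partial least squares discriminant analysis, written from scratch:
# per component the X-loading is the soft-thresholded cross-covariance
# direction retaining exactly keepX entries (renormalized), alternated with
# the Y-loading update until convergence, followed by regression-mode
# deflation of both blocks.

# soft-threshold a vector so that exactly `keep` entries stay nonzero
soft_keep <- function(a, keep) {
  p <- length(a)
  if (keep >= p) return(a)
  ab <- abs(a)
  lambda <- sort(ab, decreasing = TRUE)[keep + 1L]
  out <- sign(a) * pmax(ab - lambda, 0)
  nz <- sum(out != 0)
  if (nz != keep) {
    # ties at the threshold: fall back to a hard cut by magnitude, first
    # index wins among tied entries
    ord <- order(ab, decreasing = TRUE)
    out <- numeric(p)
    sel <- ord[seq_len(keep)]
    out[sel] <- sign(a[sel]) * (ab[sel] - lambda)
    out[sel][out[sel] == 0] <- sign(a[sel])[out[sel] == 0] * 1e-12
  }
  out
}

#' Fit a sparse PLS discriminant analysis model
#'
#' Classes are dummy (one-hot) coded and both blocks centred and scaled.
#' For each component, the algorithm alternates (a) X-loading = the
#' soft-thresholded cross-covariance direction `X'Y b`, retaining exactly
#' `keepX` nonzero entries and renormalized to unit length, and (b) the
#' Y-loading update `b = Y'X a / ||.||`, to convergence (tolerance 1e-6,
#' at most 500 iterations); both blocks are then deflated by regression on
#' the component score. Loading signs follow the convention that the
#' largest-magnitude entry of each X-loading is positive, making fits
#' reproducible across runs.
#'
#' @param X sample x feature numeric matrix (feature columns named).
#' @param y class labels (factor or coercible; >= 2 classes).
#' @param ncomp number of components.
#' @param keepX integer vector (recycled to `ncomp`) of nonzero X-loadings
#'   per component; must not exceed the feature count.
#' @param tol,max_iter inner-loop convergence controls.
#'
#' @return An object of class `splsda`: loadings (`W`), deflation loadings
#'   (`P`), Y-regression coefficients (`C`), training scores (`T`), class
#'   centroids in score space, training centring/scaling vectors, `keepX`
#'   and class levels.
#' @export
splsda_fit <- function(X, y, ncomp = 1, keepX = ncol(X), tol = 1e-6,
                       max_iter = 500) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- factor(y)
  if (nlevels(y) < 2) stop_mp("need at least 2 classes")
  levels_sorted <- sort(levels(y))
  y <- factor(y, levels = levels_sorted)
  keepX <- rep_len(keepX, ncomp)
  if (any(keepX > ncol(X))) stop_mp("keepX exceeds the feature count")
  if (any(keepX < 1)) stop_mp("keepX must be at least 1")

  xsd <- apply(X, 2, stats::sd)
  const <- xsd < 1e-12
  if (any(const)) {
    warning(sum(const), " constant feature column(s) dropped", call. = FALSE)
    X <- X[, !const, drop = FALSE]
    xsd <- xsd[!const]
  }
  if (any(keepX > ncol(X))) keepX <- pmin(keepX, ncol(X))
  xmean <- colMeans(X)
  Xc <- scale(X, center = xmean, scale = xsd)

  Yd <- stats::model.matrix(~ 0 + y)
  colnames(Yd) <- levels_sorted
  ymean <- colMeans(Yd)
  ysd <- apply(Yd, 2, stats::sd)
  Yc <- scale(Yd, center = ymean, scale = ysd)

  n <- nrow(Xc); p <- ncol(Xc); K <- ncol(Yc)
  W <- matrix(0, p, ncomp, dimnames = list(colnames(Xc), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(Xc), NULL))
  C <- matrix(0, K, ncomp, dimnames = list(levels_sorted, NULL))
  Tm <- matrix(0, n, ncomp)
  Xh <- Xc; Yh <- Yc
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xh, Yh)                    # p x K cross-covariance
    b <- svd(M, nu = 0, nv = 1)$v[, 1]
    a <- numeric(p)
    for (it in seq_len(max_iter)) {
      a_new <- drop(M %*% b)
      a_new <- soft_keep(a_new, keepX[h])
      nrm <- sqrt(sum(a_new^2))
      if (nrm < 1e-15) stop_mp("degenerate component ", h)
      a_new <- a_new / nrm
      b_new <- drop(crossprod(M, a_new))
      b_new <- b_new / sqrt(sum(b_new^2))
      if (sqrt(sum((a_new - a)^2)) < tol) { a <- a_new; b <- b_new; break }
      a <- a_new; b <- b_new
    }
    imax <- which.max(abs(a))
    if (a[imax] < 0) { a <- -a; b <- -b }
    tt <- drop(Xh %*% a)
    ss <- sum(tt^2)
    P[, h] <- drop(crossprod(Xh, tt)) / ss
    C[, h] <- drop(crossprod(Yh, tt)) / ss
    W[, h] <- a
    Tm[, h] <- tt
    Xh <- Xh - tcrossprod(tt, P[, h])
    Yh <- Yh - tcrossprod(tt, C[, h])
  }
  centroids <- apply(Tm, 2, function(col) tapply(col, y, mean))
  centroids <- matrix(centroids, nrow = K,
                      dimnames = list(levels_sorted, NULL))
  structure(list(W = W, P = P, C = C, T = Tm, centroids = centroids,
                 xmean = xmean, xsd = xsd, ymean = ymean, ysd = ysd,
                 levels = levels_sorted, keepX = keepX, ncomp = ncomp,
                 y = y),
            class = "splsda")
}

#' @export
print.splsda <- function(x, ...) {
  cat(sprintf("Sparse PLS-DA: %d component(s), keepX = (%s), classes: %s\n",
              x$ncomp, paste(x$keepX, collapse = ", "),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

splsda_scores_new <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  feats <- rownames(model$W)
  if (!all(feats %in% colnames(X_new))) {
    stop_mp("alignment error: new data lack training features")
  }
  Xc <- scale(X_new[, feats, drop = FALSE],
              center = model$xmean[feats], scale = model$xsd[feats])
  R <- model$W %*% solve(crossprod(model$P, model$W))   # rotation
  Xc %*% R
}

#' Predict classes from a sparse PLS-DA model
#'
#' Projects new samples onto the trained components (training centring and
#' scaling) and assigns a class by the maximum-distance rule (largest
#' predicted class-indicator value, the default) or by the nearest class
#' centroid in score space. Ties break deterministically to the first class
#' in sorted label order.
#'
#' @param object an [splsda_fit()] model.
#' @param newdata sample x feature matrix containing the training features.
#' @param rule "max" (predicted-indicator maximum) or "centroid".
#' @param ... unused.
#'
#' @return List with `class` (factor) and `scores` (component
#'   coordinates).
#' @export
predict.splsda <- function(object, newdata, rule = c("max", "centroid"),
                           ...) {
  rule <- match.arg(rule)
  Tn <- splsda_scores_new(object, newdata)
  if (rule == "max") {
    Yhat <- Tn %*% t(object$C)
    Yhat <- sweep(sweep(Yhat, 2, object$ysd, "*"), 2, object$ymean, "+")
    idx <- apply(Yhat, 1, which.max)   # which.max: first (sorted) class wins
  } else {
    d2 <- vapply(seq_along(object$levels), function(kk) {
      rowSums(sweep(Tn, 2, object$centroids[kk, ], "-")^2)
    }, numeric(nrow(Tn)))
    d2 <- matrix(d2, nrow = nrow(Tn))
    idx <- apply(d2, 1, which.min)
  }
  list(class = factor(object$levels[idx], levels = object$levels),
       scores = Tn)
}

#' Balanced error rate
#'
#' Mean over true classes of the within-class misclassification fraction;
#' insensitive to class imbalance. Predictions outside the true label set
#' count as errors.
#'
#' @param truth,predicted equal-length label vectors; every true class must
#'   be non-empty.
#'
#' @return Scalar in \[0, 1\].
#' @export
balanced_error_rate <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_mp("truth and predicted must have the same length")
  }
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- unique(truth)
  mean(vapply(classes, function(cl) {
    sel <- truth == cl
    mean(predicted[sel] != cl)
  }, numeric(1)))
}

stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < folds) {
      stop_mp("class '", cl, "' has fewer members than folds")
    }
    assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assign
}

#' Tune sparse PLS-DA by repeated cross-validated balanced error rate
#'
#' Stratified k-fold cross-validation with seeded reshuffles; per
#' component, sequentially chooses the `keepX` minimizing the mean BER over
#' folds and repeats (ties to the smaller `keepX`), conditioning on the
#' choices made for earlier components. Deterministic given the seed.
#'
#' @param X sample x feature matrix.
#' @param y class labels (each class needs at least `folds` members).
#' @param keepX_grid candidate keepX values (clipped to the feature count).
#' @param ncomp_max maximum number of components.
#' @param folds,repeats cross-validation design (default 3-fold, 50
#'   repeats).
#' @param seed integer seed driving the fold reshuffles.
#' @param rule prediction rule passed to [predict.splsda()].
#'
#' @return An object of class `splsda_tune`: `grid` (component, keepX, mean
#'   and SD of BER), `choice` (chosen keepX per component), `ncomp`.
#' @export
tune_splsda <- function(X, y, keepX_grid = c(1, 2, 5, 10, 25, 50, 100),
                        ncomp_max = 1, folds = 3, repeats = 50, seed = 1,
                        rule = "max") {
  X <- as.matrix(X)
  y <- factor(y)
  keepX_grid <- sort(unique(pmin(keepX_grid, ncol(X))))
  chosen <- integer(0)
  grid_rows <- list()
  for (h in seq_len(ncomp_max)) {
    ber_mat <- matrix(NA_real_, length(keepX_grid), folds * repeats)
    col <- 0L
    for (r in seq_len(repeats)) {
      set.seed(derive_seed(seed, r))
      fold_of <- stratified_folds(y, folds)
      for (f in seq_len(folds)) {
        col <- col + 1L
        test <- fold_of == f
        for (gi in seq_along(keepX_grid)) {
          fit <- splsda_fit(X[!test, , drop = FALSE], y[!test],
                            ncomp = h,
                            keepX = c(chosen, keepX_grid[gi]))
          pred <- predict(fit, X[test, , drop = FALSE], rule = rule)$class
          ber_mat[gi, col] <- balanced_error_rate(y[test], pred)
        }
      }
    }
    means <- rowMeans(ber_mat)
    sds <- apply(ber_mat, 1, stats::sd)
    best <- keepX_grid[which.min(means)]   # which.min: smaller keepX on ties
    chosen <- c(chosen, best)
    grid_rows[[h]] <- data.frame(component = h, keepX = keepX_grid,
                                 ber_mean = means, ber_sd = sds)
  }
  structure(list(grid = do.call(rbind, grid_rows), choice = chosen,
                 ncomp = ncomp_max, folds = folds, repeats = repeats),
            class = "splsda_tune")
}

#' @export
print.splsda_tune <- function(x, ...) {
  cat(sprintf("sPLS-DA tuning (%d-fold CV x %d repeats): chosen keepX = (%s)\n",
              x$folds, x$repeats, paste(x$choice, collapse = ", ")))
  print(x$grid, digits = 3)
  invisible(x)
}

#' Loading-weighted methylation score
#'
#' The per-subject biomarker derived from a sparse PLS-DA component: each
#' selected CpG's raw beta value is multiplied by its loading and the
#' products are summed. Raw (uncentred) beta values are used by default;
#' `centered = TRUE` instead applies the training centring/scaling before
#' weighting.
#'
#' @param m CpG x sample beta matrix containing every nonzero-loading
#'   probe.
#' @param model an [splsda_fit()] model whose features are probe IDs.
#' @param component component index.
#' @param centered use training-standardized beta values.
#'
#' @return Named numeric vector of per-sample scores.
#' @export
score_samples <- function(m, model, component = 1, centered = FALSE) {
  assert_beta_matrix(m)
  w <- model$W[, component]
  w <- w[w != 0]
  missing_probes <- setdiff(names(w), rownames(m))
  if (length(missing_probes)) {
    stop_mp("probe(s) absent from the matrix: ",
            paste(utils::head(missing_probes, 10), collapse = ", "))
  }
  B <- m[names(w), , drop = FALSE]
  if (centered) {
    B <- (B - model$xmean[names(w)]) / model$xsd[names(w)]
  }
  stats::setNames(as.numeric(crossprod(B, w)), colnames(m))
}
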