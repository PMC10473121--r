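# Independent oracles used across the suite. These are deliberately naive
# (brute force / closed form) and share no code with the package internals
# they check.

# Benjamini-Hochberg step-up by definition: q_(i) = min_{j >= i} p_(j)*m/j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# C-statistic by exhaustive case-control pair enumeration, ties = 1/2
cstat_pairs <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# Cox partial log-likelihood for one covariate, no ties, written out
cox_brute_hr <- function(time, event, x) {
  pll <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + x[i] * b - log(sum(exp(x[risk] * b)))
    }
    -s
  }
  exp(stats::optimize(pll, c(-20, 20), tol = 1e-10)$minimum)
}

# leading left singular direction of M = X'Y by power iteration on MM'
power_iter_direction <- function(M, iters = 2000, tol = 1e-12) {
  a <- M[, 1]
  if (sqrt(sum(a^2)) < 1e-15) a <- rnorm(nrow(M))
  a <- a / sqrt(sum(a^2))
  for (i in seq_len(iters)) {
    a_new <- M %*% crossprod(M, a)
    a_new <- a_new / sqrt(sum(a_new^2))
    if (sqrt(sum((a_new - a)^2)) < tol || sqrt(sum((a_new + a)^2)) < tol) {
      return(drop(a_new))
    }
    a <- a_new
  }
  drop(a)
}

# closed-form GLS with a known covariance built from the nested structure
gls_oracle <- function(X, y, subject, pair, s2_pair, s2_subj, s2_res) {
  n <- length(y)
  V <- diag(s2_res, n)
  for (i in 1:n) for (j in 1:n) {
    if (subject[i] == subject[j]) V[i, j] <- V[i, j] + s2_subj
    if (pair[i] == pair[j]) V[i, j] <- V[i, j] + s2_pair
  }
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X) %*% (t(X) %*% Vi %*% y))
}

# cohort_config for tiny probe universes (no planted effects by default)
tiny_cfg <- function(n_cpgs, n_pairs, seed, ...) {
  args <- utils::modifyList(
    list(n_cpgs = n_cpgs, n_pairs = n_pairs, seed = seed,
         n_stable_effect_cpgs = 0, n_interaction_cpgs = 0,
         n_crossover_cpgs = 0, n_aging_cpgs = 0, n_clock_cpgs = 0),
    list(...))
  do.call(cohort_config, args)
}

# small complete beta matrix with named dims
toy_beta <- function(nr = 4, nc = 3, values = NULL, seed = 1) {
  set.seed(seed)
  m <- matrix(if (is.null(values)) runif(nr * nc, 0.2, 0.8) else values,
              nr, nc)
  dimnames(m) <- list(sprintf("cg%08d", seq_len(nr)),
                      paste0("s", seq_len(nc)))
  m
}
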