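#' @keywords internal
"_PACKAGE"

# clamp beta values into the open unit interval before logit transforms
clip01 <- function(x, eps = 0) {
  pmin(pmax(x, eps), 1 - eps)
}

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

stop_mp <- function(...) stop(..., call. = FALSE)

assert_beta_matrix <- function(m, what = "beta matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_mp(what, " must be a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_mp(what, " must have probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop_mp(what, " has duplicated probe or sample IDs")
  }
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop_mp(what, " contains values outside [0, 1]")
  }
  invisible(m)
}

# seeds derived from a user seed must stay valid 32-bit integers
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L) + 1L)
}
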