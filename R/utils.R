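# internal numeric helpers

# rowwise log-sum-exp of a matrix, guarded against -Inf rows
row_logsumexp <- function(a) {
  m <- apply(a, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(a - m)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_prob_rows <- function(m, tol = 1e-8, what = "matrix") {
  if (any(m < -tol) || any(m > 1 + tol)) {
    rlang::abort(sprintf("%s has entries outside [0, 1]", what))
  }
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol)) {
    rlang::abort(sprintf("rows of %s must sum to 1 (max deviation %.2e)",
                         what, max(abs(rs - 1))))
  }
  invisible(TRUE)
}

# seeded evaluation that leaves the caller's RNG untouched; seed = NULL
# falls through to the ambient RNG state
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
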