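#' Round half up
#'
#' Deterministic rounding with ties away from zero (for positive input,
#' half up). Used for every fractional subset size in the package so that
#' split and pool sizes follow one convention, e.g. `0.75 * 198 = 148.5`
#' becomes 149.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @examples
#' round_half_up(c(148.5, 74.25, 222.75))
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Derive a reproducible child seed from a root seed and integer indices.
# Linear-congruential mixing kept below 2^31 - 1 so the result is always a
# valid R integer seed; doubles are exact here (products < 2^53).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Fixed label ordering used for every tie-break in the package:
# lexicographic sort of the label set (C locale via stringr-free sort).
label_order <- function(labels) {
  sort(unique(as.character(labels)), method = "radix")
}

# Majority vote over a character matrix (rows = samples, cols = voters).
# Returns the modal label per row; ties broken by the lowest label in
# `levels` (a fixed ordering).
vote_modal <- function(votes, levels) {
  apply(votes, 1L, function(v) {
    tab <- table(factor(v, levels = levels))
    levels[which.max(tab)]  # which.max takes the first (lowest) on ties
  })
}

# Modal label and its vote share per row.
vote_share <- function(votes, levels) {
  modal <- vote_modal(votes, levels)
  share <- vapply(seq_len(nrow(votes)), function(r) {
    mean(votes[r, ] == modal[r])
  }, numeric(1))
  list(label = modal, share = share)
}
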