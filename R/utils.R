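# Canonical one-letter amino-acid alphabet, alphabetical order.
# Enumeration order and tie-breaking downstream rely on this ordering.
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The twenty canonical amino acids
#'
#' One-letter codes in alphabetical order. This is the fixed alphabet used
#' by [enumerate_saturation()] and all variant parsing; stop codons,
#' ambiguity codes and non-standard residues are rejected.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() AA_CODES

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# Squared Euclidean distances between rows of a and rows of b, blockwise so
# that large variant sets never materialize an N x N matrix at once.
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
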