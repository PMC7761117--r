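# Binary-word utilities shared by all modules.
#
# State words of an N-node system are encoded as integers 0 .. 2^N - 1,
# with node i mapped to bit i - 1 (node 1 = least significant bit).
# Probability tables over words are numeric vectors of length 2^N indexed
# by word + 1; the all-ones word is 2^N - 1 (last element).

#' Bit matrix of all words of an N-node system
#'
#' Returns the `2^N x N` 0/1 matrix whose row `w + 1` holds the node states
#' of word `w` under the package's encoding (node `i` = bit `i - 1`).
#'
#' @param n_nodes number of nodes (N >= 1).
#' @return integer matrix with `2^n_nodes` rows and `n_nodes` columns.
#' @export
#' @examples
#' word_bits(2)
word_bits <- function(n_nodes) {
  stopifnot(length(n_nodes) == 1L, n_nodes >= 1, n_nodes == round(n_nodes))
  w <- 0:(2^n_nodes - 1)
  vapply(seq_len(n_nodes), function(i) as.integer((w %/% 2^(i - 1)) %% 2),
         integer(2^n_nodes))
}

#' Word labels as binary strings
#'
#' Human-readable labels for the `2^N` words, written with node 1 leftmost
#' (so `"10"` for N = 2 means node 1 active, node 2 silent).
#'
#' @inheritParams word_bits
#' @return character vector of length `2^n_nodes`.
#' @export
word_labels <- function(n_nodes) {
  b <- word_bits(n_nodes)
  apply(b, 1L, paste0, collapse = "")
}

# Subsystem word index (0-based) of every full-system word, for the nodes
# in `nodes`. nodes[j] maps to bit j - 1 of the subsystem word.
word_project <- function(nodes, n_nodes) {
  b <- word_bits(n_nodes)
  as.integer(b[, nodes, drop = FALSE] %*% 2^(seq_along(nodes) - 1))
}

# Clamp tiny negative round-off (within -tol) to exactly 0; error beyond.
clamp_prob <- function(p, tol = 1e-12, what = "probability") {
  bad <- p < -tol
  if (any(bad)) {
    stop(sprintf("%s has negative entries (min %.3e)", what, min(p)), call. = FALSE)
  }
  p[p < 0] <- 0
  p
}
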