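#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster labelings of the same
#' items; 1 for identical partitions (up to label permutation), ~0 for
#' independent ones. Used to score recovery of planted sample groups.
#'
#' @param a,b Vectors of cluster labels, equal length.
#' @return Numeric scalar.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
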