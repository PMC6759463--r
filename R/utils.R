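# Internal helpers shared across stages.

# Per-locus alternate-allele frequency over non-missing calls.
allele_freq <- function(calls) colMeans(calls, na.rm = TRUE) / 2

# Mean-impute missing calls per locus (PCA / k-means / DAPC only; likelihood
# methods skip missing calls exactly).
impute_mean <- function(calls) {
  mu <- colMeans(calls, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(calls))
  if (length(idx)) calls[idx] <- mu[(idx - 1L) %/% nrow(calls) + 1L]
  calls
}

# Center and scale loci; zero-variance loci are centered only.
scale_loci <- function(calls) {
  s <- apply(calls, 2, stats::sd)
  s[s == 0 | is.na(s)] <- 1
  scale(calls, center = TRUE, scale = s)
}

# Derive a stream of child seeds from one master seed (keeps every derived
# seed a valid 32-bit integer).
derive_seeds <- function(seed, n, stream = 0L) {
  (as.numeric(seed) * 7919 + stream * 104729 + seq_len(n) * 2654435761) %%
    2147483647
}

# Adjusted Rand index between two labelings (used by tests and reported by
# the pipeline when truth labels are available).
#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster labelings of the same
#' samples; 1 means identical partitions up to relabeling, 0 is the expected
#' value under independent random partitions.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A number (at most 1).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
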