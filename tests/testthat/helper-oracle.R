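# Dense brute-force oracles, independent of the sparse implementation.

# Dense k-mer count vector of length l^k by explicit enumeration over
# every window (0 counts for windows touching an invalid position).
dense_counts <- function(seq, scheme, k) {
  red <- reduce_sequence(seq, scheme)
  l <- scheme$alphabet_size
  v <- numeric(l^k)
  n <- length(red$symbols)
  if (n >= k) {
    for (p in seq_len(n - k + 1)) {
      win <- red$symbols[p:(p + k - 1)]
      if (anyNA(win)) next
      idx <- 1
      for (g in win) idx <- (idx - 1) * l + g  # mixed-radix rank, 1-based
      v[idx] <- v[idx] + 1
    }
  }
  v
}

dense_normalize <- function(v, normalization) {
  if (normalization == "raw" || sum(v) == 0) return(v)
  if (normalization == "frequency") return(v / sum(v))
  if (normalization == "l2") return(v / sqrt(sum(v^2)))
  stop("bad normalization")
}

# Gaussian kernel matrix by dense enumeration.
dense_gaussian_kernel <- function(seqs, scheme, k, gamma,
                                  normalization = "l2") {
  V <- sapply(seqs, function(s)
    dense_normalize(dense_counts(s, scheme, k), normalization))
  V <- matrix(V, ncol = length(seqs))
  n <- length(seqs)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    K[i, j] <- exp(-gamma * sum((V[, i] - V[, j])^2))
  K
}

random_protein <- function(len, alphabet = CANONICAL_RESIDUES)
  paste(sample(alphabet, len, replace = TRUE), collapse = "")

# Small labeled dataset with a strong planted signal, for classifier
# and CV tests that need to run in seconds.
tiny_motif_dataset <- function(n_per_class = 12, seed = 11,
                               mutation_rate = 0, n_classes = 2) {
  generate_dataset(generator_config(
    n_classes = n_classes, per_class_sizes = rep(n_per_class, n_classes),
    length_range = c(60, 120), mutation_rate = mutation_rate, seed = seed))
}
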