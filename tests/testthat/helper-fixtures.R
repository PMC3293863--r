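# Shared fixtures built in code.

# A "plain" world: K well-separated subgroups, no age effects, no skewed
# markers. Used wherever the stated conditions are just subgroups + separation.
plain_spec <- function(n_train = 300, n_valid = 300, K = 3, n_markers = 10,
                       separation = 6, seed = 1L, ...) {
  generator_spec(n_train = n_train, n_valid = n_valid, n_markers = n_markers,
                 n_subgroups = K,
                 separation = separation,
                 skewed_markers = integer(0),
                 marker_scales = rep(1, n_markers),
                 marker_offsets = rep(0, n_markers),
                 age_slopes = rep(0, n_markers),
                 n_traits = 3, seed = seed, ...)
}

# A small cohort with gaussian markers, directly constructed.
gaussian_cohort <- function(n = 50, P = 5, seed = 1L) {
  set.seed(seed)
  cohort_matrix(paste0("s", seq_len(n)), runif(n, 20, 80),
                matrix(rnorm(n * P), n, P))
}

# Map each cluster label to the majority truth label among its members
# (used to score over-partitioned clusterings such as a too-large SOM grid).
majority_map_labels <- function(labels, truth) {
  out <- rep(NA_integer_, length(labels))
  for (k in unique(labels[!is.na(labels)])) {
    idx <- which(labels == k)
    out[idx] <- as.integer(names(which.max(table(truth[idx]))))
  }
  out
}

# Independent double-loop oracle for homogeneity / separation.
quality_oracle <- function(X, lab) {
  keep <- !is.na(lab)
  X <- X[keep, , drop = FALSE]; lab <- lab[keep]
  ks <- sort(unique(lab))
  cen <- lapply(ks, function(k) colMeans(X[lab == k, , drop = FALSE]))
  H <- 0
  for (i in seq_len(nrow(X)))
    H <- H + cor(X[i, ], cen[[match(lab[i], ks)]])
  H <- H / nrow(X)
  if (length(ks) == 1) return(list(H_A = H, S_A = 0, diff = H))
  sizes <- sapply(ks, function(k) sum(lab == k))
  num <- 0; den <- 0
  for (i in seq_len(length(ks) - 1)) for (j in (i + 1):length(ks)) {
    num <- num + sizes[i] * sizes[j] * cor(cen[[i]], cen[[j]])
    den <- den + sizes[i] * sizes[j]
  }
  list(H_A = H, S_A = num / den, diff = H - num / den)
}

# Brute-force hypergeometric upper tail by enumerating all cluster draws.
hypergeom_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  pos <- seq_len(K)  # first K population members are positives
  hits <- apply(draws, 2, function(d) sum(d %in% pos) >= k)
  mean(hits)
}
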