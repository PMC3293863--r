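#' Construct a clustering result
#'
#' The common assignment contract of the three algorithms: every input sample
#' id carries exactly one label in `1..K`, or `NA` for unclassified samples
#' (only the graph-based algorithm produces those). Labels are compacted to be
#' dense in `1..K`.
#'
#' @param sample_ids character vector of sample ids.
#' @param labels integer-ish vector, same length; `NA` = unclassified.
#' @param algorithm,params,seed provenance fields.
#' @param compact renumber labels densely as `1..K` (default). Projected
#'   clusterings pass `FALSE` so cluster identities stay aligned with the
#'   training labels even when some training cluster is empty on the
#'   validation side.
#' @return An object of class `clustering`.
#' @export
clustering <- function(sample_ids, labels, algorithm = "unknown",
                       params = list(), seed = NA_integer_, compact = TRUE) {
  stopifnot(length(sample_ids) == length(labels))
  lab <- if (compact) as.integer(factor(labels)) else as.integer(labels)
  names(lab) <- as.character(sample_ids)
  k <- if (all(is.na(lab))) 0L else max(lab, na.rm = TRUE)
  structure(list(sample_ids = as.character(sample_ids), labels = lab,
                 k = k, algorithm = algorithm, params = params, seed = seed),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat(sprintf("<clustering> %s: %d samples, K = %d, %d unclassified\n",
              x$algorithm, length(x$labels), x$k, sum(is.na(x$labels))))
  invisible(x)
}

#' Cluster sizes of a clustering
#' @param cl a [clustering()].
#' @return Integer vector of length K.
#' @export
cluster_sizes <- function(cl) tabulate(cl$labels, nbins = cl$k)

# k-means++ seeding: spread initial centers proportionally to squared distance
# from the nearest already-chosen center.
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) i <- sample.int(n, 1)
    else i <- sample.int(n, 1, prob = d2)
    centers[j + 1, ] <- X[i, ]
    d2 <- pmin(d2, rowSums((X - matrix(X[i, ], n, ncol(X), byrow = TRUE))^2))
  }
  centers
}

#' K-means clustering with k-means++ restarts
#'
#' Lloyd iterations from k-means++ initializations, keeping the best of
#' `restarts` runs by total within-cluster sum of squares. Deterministic under
#' a fixed seed; never leaves samples unclassified.
#'
#' @param cohort a preprocessed [cohort_matrix()].
#' @param k number of clusters (conventionally taken from the graph
#'   clustering of the same pre-processing variant).
#' @param seed integer seed.
#' @param restarts number of restarts (default 10).
#' @param iter_max Lloyd iteration cap per restart.
#' @return A [clustering()].
#' @export
kmeans_cluster <- function(cohort, k, seed = 1L, restarts = 10, iter_max = 100) {
  X <- cohort$markers
  if (k > nrow(X)) stop("k exceeds the number of samples")
  if (k < 1) stop("k must be >= 1")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- .kmeanspp_init(X, k)
    init <- init[!duplicated(init), , drop = FALSE]
    fit <- suppressWarnings(
      stats::kmeans(X, centers = init, iter.max = iter_max,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  clustering(cohort$sample_ids, best$cluster, "kmeans",
             params = list(k = k, restarts = restarts), seed = seed)
}

# closest-to-square factorization rows x cols = n_cells
.som_grid <- function(n_cells) {
  r <- max(which(n_cells %% seq_len(floor(sqrt(n_cells))) == 0))
  c(r, n_cells %/% r)
}

#' Batch self-organizing map clustering
#'
#' Prototypes live on a rectangular grid whose rows x cols is the
#' factorization of `n_cells` closest to square. Batch training for `epochs`
#' rounds with a Gaussian neighborhood whose radius shrinks linearly from
#' `max(grid dims) / 2` to 0.5. Each sample is labeled by its best-matching
#' unit; empty cells are dropped and labels compacted, so the realized number
#' of clusters is at most `n_cells`.
#'
#' @param cohort a preprocessed [cohort_matrix()].
#' @param n_cells total number of map cells.
#' @param seed integer seed (prototype initialization).
#' @param epochs training epochs (default 50).
#' @return A [clustering()].
#' @export
som_cluster <- function(cohort, n_cells, seed = 1L, epochs = 50) {
  X <- cohort$markers
  n <- nrow(X)
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (n_cells > n)
    warning("more map cells than samples; empty cells will be dropped")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  g <- .som_grid(n_cells)
  grid <- as.matrix(expand.grid(row = seq_len(g[1]), col = seq_len(g[2])))
  D2grid <- as.matrix(stats::dist(grid))^2
  W <- X[sample.int(n, n_cells, replace = n_cells > n), , drop = FALSE]
  sigma0 <- max(g) / 2
  x2 <- rowSums(X^2)
  for (t in seq_len(epochs)) {
    sigma <- sigma0 + (0.5 - sigma0) * (t - 1) / max(epochs - 1, 1)
    # BMU per sample via squared Euclidean distance
    d <- outer(x2, rowSums(W^2), "+") - 2 * tcrossprod(X, W)
    bmu <- max.col(-d, ties.method = "first")
    H <- exp(-D2grid / (2 * sigma^2))        # cells x cells
    A <- H[bmu, , drop = FALSE]              # n x cells
    denom <- colSums(A)
    nz <- denom > 0
    W[nz, ] <- crossprod(A[, nz, drop = FALSE], X) / denom[nz]
  }
  d <- outer(x2, rowSums(W^2), "+") - 2 * tcrossprod(X, W)
  bmu <- max.col(-d, ties.method = "first")
  clustering(cohort$sample_ids, bmu, "som",
             params = list(n_cells = n_cells, grid = g, epochs = epochs),
             seed = seed)
}
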