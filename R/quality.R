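#' Homogeneity, separation and their difference for a clustering
#'
#' Homogeneity `H_A` is the mean similarity between each clustered sample and
#' the centroid of its cluster; separation `S_A` is the size-weighted mean
#' similarity between centroids of different clusters:
#' `S_A = sum_{i<j} n_i n_j sim(c_i, c_j) / sum_{i<j} n_i n_j`.
#' Similarity is Pearson correlation, matching the graph clustering's
#' default, so both statistics live in \[-1, 1\] and their difference
#' `H_A - S_A` is the single-number quality score (higher = compact and
#' well-separated). Unclassified samples are excluded from both statistics.
#' With a single cluster, `S_A` is defined as 0.
#'
#' @param cohort the preprocessed [cohort_matrix()] the clustering was built
#'   on.
#' @param cl a [clustering()].
#' @return A list: `H_A`, `S_A`, `diff`, `K`.
#' @export
cluster_quality <- function(cohort, cl) {
  lab <- cl$labels[cohort$sample_ids]
  keep <- !is.na(lab)
  if (!any(keep)) stop("clustering has no classified samples")
  X <- cohort$markers[keep, , drop = FALSE]
  lab <- lab[keep]
  ks <- sort(unique(lab))
  cen <- t(vapply(ks, function(k)
    colMeans(X[lab == k, , drop = FALSE]), numeric(ncol(X))))
  for (i in seq_along(ks))
    if (stats::sd(cen[i, ]) == 0)
      stop(sprintf("cluster %d has a constant centroid: correlation undefined",
                   ks[i]))
  H <- mean(vapply(seq_len(nrow(X)), function(i)
    .safe_cor(X[i, ], cen[match(lab[i], ks), ], "sample vector"), numeric(1)))
  if (length(ks) == 1) {
    S <- 0
  } else {
    sizes <- as.numeric(table(factor(lab, levels = ks)))
    Csim <- stats::cor(t(cen))
    num <- 0; den <- 0
    for (i in seq_len(length(ks) - 1)) for (j in (i + 1):length(ks)) {
      w <- sizes[i] * sizes[j]
      num <- num + w * Csim[i, j]
      den <- den + w
    }
    S <- num / den
  }
  list(H_A = H, S_A = S, diff = H - S, K = length(ks))
}

# One pipeline run on a (sub)cohort: preprocess -> cluster -> quality.
.run_pipeline_once <- function(cohort, variant, algorithm, k, click,
                               seed, aggregate_transforms = FALSE,
                               som_epochs = 50, kmeans_restarts = 10) {
  pp <- preprocess(cohort, variant, aggregate_transforms = aggregate_transforms)
  cl <- switch(algorithm,
    click = {
      cp <- click
      cp$seed <- as.integer(seed)
      click_cluster(pp$cohort, cp)
    },
    kmeans = kmeans_cluster(pp$cohort, k, seed = seed,
                            restarts = kmeans_restarts),
    som = som_cluster(pp$cohort, k, seed = seed, epochs = som_epochs),
    stop(sprintf("unknown algorithm '%s'", algorithm)))
  # K = 0 (all unclassified) is a legitimate graph-clustering outcome on
  # unstructured data; report it as an empty-quality row rather than failing
  q <- if (all(is.na(cl$labels)))
    list(H_A = NA_real_, S_A = NA_real_, diff = NA_real_, K = 0L)
  else cluster_quality(pp$cohort, cl)
  list(pp = pp, cl = cl, q = q)
}

#' Resampled cluster-quality summary for one pipeline
#'
#' Reruns the full preprocess -> cluster -> quality pipeline `n_reps` times,
#' each time dropping `floor(frac * n)` samples uniformly at random (3%
#' dropout by default), and summarizes the quality difference `H_A - S_A` and
#' realized cluster count over repetitions. The full-data run is reported
#' alongside.
#'
#' @param cohort the raw [cohort_matrix()] (pre-processing is refit per run).
#' @param variant one of [pipeline_variants()].
#' @param algorithm `"click"`, `"kmeans"` or `"som"`.
#' @param k cluster count for k-means / map cells for the SOM (conventionally
#'   the realized K of the graph clustering under the same variant); ignored
#'   for `"click"`.
#' @param frac dropout fraction per repetition (default 0.03).
#' @param n_reps number of repetitions (default 10).
#' @param seed integer seed; repetition `i` derives seed `seed + i`, and the
#'   full-data run uses `seed + 1`, so `frac = 0` reproduces the full-data
#'   result exactly.
#' @param click a [click_params()] used when `algorithm = "click"`.
#' @param ... passed to the pipeline runner (e.g. `aggregate_transforms`,
#'   `som_epochs`, `kmeans_restarts`).
#' @return A list of class `quality_summary`: full-data `H_A`, `S_A`, `diff`,
#'   `K`, `clustering`, plus `resampled` (data.frame of `diff`, `K`) and
#'   `mean_diff`, `sd_diff`, `mean_K`, `sd_K`.
#' @export
quality_resample <- function(cohort, variant, algorithm, k = NULL,
                             frac = 0.03, n_reps = 10, seed = 1L,
                             click = click_params(), ...) {
  if (frac < 0 || frac >= 1) stop("frac must be in [0, 1)")
  if (algorithm %in% c("kmeans", "som") && is.null(k))
    stop("k is required for kmeans/som")
  full <- .run_pipeline_once(cohort, variant, algorithm, k, click,
                             seed = seed + 1L, ...)
  n <- length(cohort$sample_ids)
  n_drop <- floor(frac * n)
  reps <- vector("list", n_reps)
  old <- .save_rng(); on.exit(.restore_rng(old))
  for (i in seq_len(n_reps)) {
    set.seed(seed + 1000L + i)
    keep <- if (n_drop > 0) sort(sample.int(n, n - n_drop)) else seq_len(n)
    sub <- cohort_subset(cohort, keep)
    r <- .run_pipeline_once(sub, variant, algorithm, k, click,
                            seed = seed + i, ...)
    reps[[i]] <- c(diff = r$q$diff, K = r$q$K)
  }
  res <- as.data.frame(do.call(rbind, reps))
  structure(list(H_A = full$q$H_A, S_A = full$q$S_A, diff = full$q$diff,
                 K = full$q$K, clustering = full$cl, preprocess = full$pp,
                 resampled = res,
                 mean_diff = mean(res$diff), sd_diff = stats::sd(res$diff),
                 mean_K = mean(res$K), sd_K = stats::sd(res$K),
                 variant = variant, algorithm = algorithm, seed = seed),
            class = "quality_summary")
}

#' @export
print.quality_summary <- function(x, ...) {
  cat(sprintf(
    "<quality_summary> %s/%s: K = %d, H_A - S_A = %.3f (resampled %.3f +/- %.3f, K %.1f +/- %.1f)\n",
    x$variant, x$algorithm, x$K, x$diff, x$mean_diff, x$sd_diff,
    x$mean_K, x$sd_K))
  invisible(x)
}

#' Student's t comparison of two resampled quality summaries
#'
#' Two-sample equal-variance t-test (Welch by option) on the resampled
#' `H_A - S_A` lists of two pipelines.
#'
#' @param a,b `quality_summary` objects (or plain numeric vectors of
#'   resampled differences).
#' @param welch use the unequal-variance form instead of the classical
#'   pooled-variance Student's test.
#' @return A list: `t`, `p` (two-sided), `df`, and `degenerate` (TRUE when
#'   the pooled variance is zero).
#' @export
compare_quality <- function(a, b, welch = FALSE) {
  xa <- if (inherits(a, "quality_summary")) a$resampled$diff else as.numeric(a)
  xb <- if (inherits(b, "quality_summary")) b$resampled$diff else as.numeric(b)
  n1 <- length(xa); n2 <- length(xb)
  if (n1 < 2 || n2 < 2) stop("need >= 2 resampled values per group")
  m1 <- mean(xa); m2 <- mean(xb)
  v1 <- stats::var(xa); v2 <- stats::var(xb)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) return(list(t = 0, p = 1, df = n1 + n2 - 2, degenerate = TRUE))
    return(list(t = sign(m1 - m2) * Inf, p = 0, df = n1 + n2 - 2,
                degenerate = TRUE))
  }
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tt, p = 2 * stats::pt(-abs(tt), df), df = df, degenerate = FALSE)
}
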