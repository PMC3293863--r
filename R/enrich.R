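#' Upper-tail hypergeometric probability
#'
#' `P(X >= k_in)` where `X ~ Hypergeometric(N, K_trait, n_cluster)`: the
#' chance of seeing at least `k_in` trait-positive samples in a cluster of
#' size `n_cluster` drawn from a population of `N` samples containing
#' `K_trait` positives. Computed by direct summation of the point masses.
#'
#' @param N population size.
#' @param K_trait trait positives in the population.
#' @param n_cluster cluster size.
#' @param k_in trait positives inside the cluster.
#' @return The upper-tail probability.
#' @export
hypergeom_pvalue <- function(N, K_trait, n_cluster, k_in) {
  if (any(c(N, K_trait, n_cluster, k_in) < 0) || K_trait > N ||
      n_cluster > N || k_in > min(K_trait, n_cluster))
    stop("inconsistent hypergeometric counts")
  hi <- min(K_trait, n_cluster)
  if (k_in == 0) return(1)
  sum(stats::dhyper(k_in:hi, K_trait, N - K_trait, n_cluster))
}

#' Per-cluster hypergeometric trait enrichment
#'
#' One over-representation test per (cluster, trait) pair. For each trait the
#' tested population is the clustered samples with known trait status; traits
#' with fewer than `min_positives` positives in that population are excluded.
#' The enrichment factor is the trait's frequency in the cluster divided by
#' its frequency in the whole tested population. All records are returned
#' with an explicit significance flag (`p < alpha`, optionally after
#' Benjamini-Hochberg adjustment).
#'
#' @param cl a [clustering()].
#' @param tt a [trait_table()] sharing sample ids with the clustering.
#' @param alpha significance level (default 0.05, unadjusted).
#' @param min_positives minimum trait positives in the tested population
#'   (default 30).
#' @param bh apply Benjamini-Hochberg adjustment across all tests before
#'   flagging significance (default FALSE: raw per-test p-values).
#' @return A data.frame of enrichment records: `cluster`, `trait`, `N`,
#'   `K_trait`, `n_cluster`, `k_in`, `p`, `factor`, `significant`.
#' @export
enrich_clusters <- function(cl, tt, alpha = 0.05, min_positives = 30,
                            bh = FALSE) {
  ids <- intersect(cl$sample_ids, tt$sample_ids)
  if (length(ids) == 0) stop("clustering and trait table share no sample ids")
  lab <- cl$labels[ids]
  tr <- tt$traits[ids, , drop = FALSE]
  clustered <- !is.na(lab)
  recs <- list()
  for (trait in colnames(tr)) {
    known <- clustered & !is.na(tr[, trait])
    N <- sum(known)
    K_trait <- sum(tr[known, trait])
    if (N == 0 || K_trait < min_positives) next
    for (k in sort(unique(lab[known]))) {
      inc <- known & lab == k
      n_cluster <- sum(inc)
      k_in <- sum(tr[inc, trait])
      p <- hypergeom_pvalue(N, K_trait, n_cluster, k_in)
      recs[[length(recs) + 1L]] <- data.frame(
        cluster = k, trait = trait, N = N, K_trait = K_trait,
        n_cluster = n_cluster, k_in = k_in, p = p,
        factor = (k_in / n_cluster) / (K_trait / N))
    }
  }
  if (!length(recs))
    return(data.frame(cluster = integer(0), trait = character(0),
                      N = integer(0), K_trait = integer(0),
                      n_cluster = integer(0), k_in = integer(0),
                      p = numeric(0), factor = numeric(0),
                      significant = logical(0)))
  out <- do.call(rbind, recs)
  padj <- if (bh) stats::p.adjust(out$p, "BH") else out$p
  out$significant <- padj < alpha
  out[order(out$p), , drop = FALSE]
}

#' Cross-cohort validated-enrichment accounting
#'
#' Compares enrichment records from the training cohort and the projected
#' validation cohort (which share cluster labels by construction). A *valid
#' enrichment* is a (cluster, trait) pair significant in both cohorts; a
#' *validated cluster* holds at least one valid enrichment; the *pipeline
#' enrichment factor* is the mean validation-cohort factor of the three
#' smallest-p (validation side) valid enrichments.
#'
#' @param train_records,valid_records data.frames from [enrich_clusters()]
#'   on the training and validation cohorts.
#' @return A list of class `validation_report`: counts (`total_train`,
#'   `valid`, `distinct_train`, `distinct_valid`, `enriched_clusters`,
#'   `validated_clusters`, `pipeline_factor`), display strings in
#'   `ratio_total` / `ratio_distinct` / `ratio_clusters` form, and the valid
#'   record pairs in `valid_records`.
#' @export
validate_enrichments <- function(train_records, valid_records) {
  sig_t <- train_records[train_records$significant, , drop = FALSE]
  sig_v <- valid_records[valid_records$significant, , drop = FALSE]
  key_t <- paste(sig_t$cluster, sig_t$trait, sep = "\r")
  key_v <- paste(sig_v$cluster, sig_v$trait, sep = "\r")
  valid_keys <- intersect(key_t, key_v)
  vt <- sig_t[key_t %in% valid_keys, , drop = FALSE]
  vv <- sig_v[key_v %in% valid_keys, , drop = FALSE]
  vv <- vv[order(vv$p), , drop = FALSE]
  pipeline_factor <- if (nrow(vv)) mean(vv$factor[seq_len(min(3, nrow(vv)))])
                     else NA_real_
  rpt <- list(
    total_train = nrow(sig_t),
    valid = length(valid_keys),
    distinct_train = length(unique(sig_t$trait)),
    distinct_valid = length(unique(vt$trait)),
    enriched_clusters = length(unique(sig_t$cluster)),
    validated_clusters = length(unique(vt$cluster)),
    pipeline_factor = pipeline_factor,
    valid_records = vv)
  rpt$ratio_total <- sprintf("%d/%d", rpt$valid, rpt$total_train)
  rpt$ratio_distinct <- sprintf("%d/%d", rpt$distinct_valid, rpt$distinct_train)
  rpt$ratio_clusters <- sprintf("%d/%d", rpt$validated_clusters,
                                rpt$enriched_clusters)
  structure(rpt, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> valid %s, distinct %s, clusters %s, factor %.2f\n",
    x$ratio_total, x$ratio_distinct, x$ratio_clusters, x$pipeline_factor))
  invisible(x)
}
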