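#' Parameters for the CLICK-style graph clustering
#'
#' @param homogeneity minimum mean within-component similarity for a
#'   component to be accepted as a kernel (correlation scale, in (-1, 1)).
#'   `NULL` (the default) self-calibrates to the fitted mixture's crossing
#'   point — the similarity at which a pair is equally likely to be mates or
#'   non-mates — so a kernel must look like mates on average.
#' @param min_kernel minimum kernel size (>= 2); smaller fragments join the
#'   singleton pool and can only re-enter clusters by adoption. Capped at the
#'   sample count for tiny inputs.
#' @param adoption minimum average similarity between a singleton and a
#'   kernel's members for adoption; `NULL` self-calibrates as above.
#' @param merge minimum centroid similarity for two kernels to be merged;
#'   `NULL` self-calibrates as above.
#' @param em_max_iter,em_tol EM settings for the two-component
#'   (mates / non-mates) normal mixture fitted to the similarity distribution.
#' @param similarity `"pearson"` (correlation of preprocessed marker vectors,
#'   the default) or `"euclidean"` (negated distance; thresholds then live on
#'   that scale).
#' @param exact_cut_max largest component size on which the exact global
#'   minimum cut (Stoer-Wagner) is computed; larger components use the
#'   deterministic spectral-bisection / weakest-vertex cut candidates (see
#'   [click_cluster()]).
#' @param seed integer seed (EM initialization is deterministic, the seed is
#'   recorded for provenance).
#' @return A list of class `click_params`.
#' @export
click_params <- function(homogeneity = NULL, min_kernel = 5, adoption = NULL,
                         merge = NULL, em_max_iter = 100, em_tol = 1e-8,
                         similarity = c("pearson", "euclidean"),
                         exact_cut_max = 100, seed = 1L) {
  similarity <- match.arg(similarity)
  if (min_kernel < 2) stop("min_kernel must be >= 2")
  thr <- c(homogeneity, adoption, merge)  # NULLs drop out
  if (similarity == "pearson" && length(thr) && any(abs(thr) >= 1))
    stop("correlation-scale thresholds must lie in (-1, 1)")
  structure(list(homogeneity = homogeneity, min_kernel = min_kernel,
                 adoption = adoption, merge = merge,
                 em_max_iter = em_max_iter, em_tol = em_tol,
                 similarity = similarity, exact_cut_max = exact_cut_max,
                 seed = as.integer(seed)),
            class = "click_params")
}

# Two-component normal mixture on the similarity values by EM, with a pooled
# variance. The pooled form is deliberately restrictive: with heavily
# overlapping mates / non-mates distributions an unconstrained fit chases the
# upper tail, which starves same-cluster pairs of positive weight and
# shatters genuine clusters. Returns NULL when the components do not separate
# (degenerate data); the caller then falls back to a fixed cutoff.
.sim_mixture_em <- function(s, max_iter, tol) {
  sdev <- stats::sd(s)
  if (!is.finite(sdev) || sdev < 1e-10) return(NULL)
  q <- stats::quantile(s, 0.8, names = FALSE)
  hi <- s >= q
  if (!any(hi) || all(hi)) return(NULL)
  p <- mean(hi)
  mu1 <- mean(s[hi]); mu0 <- mean(s[!hi])
  sig <- max(sdev / 2, 1e-8)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- p * stats::dnorm(s, mu1, sig)
    d0 <- (1 - p) * stats::dnorm(s, mu0, sig)
    tot <- d1 + d0
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    ll <- sum(log(tot))
    p <- mean(g)
    if (p < 1e-8 || p > 1 - 1e-8) return(NULL)
    mu1 <- sum(g * s) / sum(g)
    mu0 <- sum((1 - g) * s) / sum(1 - g)
    sig <- sqrt(mean(g * (s - mu1)^2 + (1 - g) * (s - mu0)^2))
    sig <- max(sig, 1e-8)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  if (mu1 < mu0) { # enforce mates = high-similarity component
    tmp <- mu1; mu1 <- mu0; mu0 <- tmp
    p <- 1 - p
  }
  # components must be genuinely separated relative to the overall spread,
  # otherwise the likelihood-ratio weights are numerically meaningless
  if (mu1 - mu0 < 0.1 * sdev) return(NULL)
  list(p = p, mu1 = mu1, sd1 = sig, mu0 = mu0, sd0 = sig)
}

# Log-likelihood-ratio edge weights from the fitted mixture.
.mixture_weights <- function(S, fit) {
  s <- as.vector(S)
  w <- log(fit$p) + stats::dnorm(s, fit$mu1, fit$sd1, log = TRUE) -
    log(1 - fit$p) - stats::dnorm(s, fit$mu0, fit$sd0, log = TRUE)
  matrix(w, nrow(S))
}

# Positive-edge connected components of the index set `idx` under weights W.
.pos_components <- function(W, idx) {
  sub <- W[idx, idx, drop = FALSE] > 0
  diag(sub) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  comp <- igraph::components(g)$membership
  split(idx, comp)
}

# Global minimum-weight cut of the positive subgraph over `idx`
# (Stoer-Wagner). Returns the two index sets.
.min_cut_split <- function(W, idx) {
  sub <- W[idx, idx, drop = FALSE]
  sub[sub < 0] <- 0
  diag(sub) <- 0
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                           weighted = TRUE)
  ct <- igraph::min_cut(g, capacity = igraph::E(g)$weight, value.only = FALSE)
  list(a = idx[as.integer(ct$partition1)], b = idx[as.integer(ct$partition2)])
}

# Deterministic spectral bisection of the full-weight submatrix: split by the
# sign of the leading eigenvector (fixed-start power iteration). Finds the
# cut that the full log-likelihood weights "want" (blocks of positive weights
# stay together, negative blocks separate). NULL when degenerate or one-sided.
.spectral_split <- function(Wsub) {
  n <- nrow(Wsub)
  x <- sin(seq_len(n))
  for (i in seq_len(40)) {
    x <- Wsub %*% x
    nx <- sqrt(sum(x^2))
    if (nx < 1e-12) return(NULL)
    x <- x / nx
  }
  a <- which(x > 0)
  if (length(a) == 0 || length(a) == n) return(NULL)
  list(a = a, b = which(x <= 0))
}

# Candidate cuts for one connected component, ranked by full cut weight
# (sum of mixture weights over all crossing pairs, negative non-edges
# included). Small components get the exact global min cut of the positive
# subgraph; large components use two deterministic candidates: the
# weakest-vertex cut and the spectral bisection.
.component_cuts <- function(W, comp, exact_max) {
  cuts <- list()
  if (length(comp) <= exact_max) {
    cuts[[length(cuts) + 1L]] <- .min_cut_split(W, comp)
  }
  Wsub <- W[comp, comp, drop = FALSE]
  sp <- .spectral_split(Wsub)
  if (!is.null(sp))
    cuts[[length(cuts) + 1L]] <- list(a = comp[sp$a], b = comp[sp$b])
  Wpos <- Wsub; Wpos[Wpos < 0] <- 0
  v <- which.min(rowSums(Wpos))[1]
  cuts[[length(cuts) + 1L]] <- list(a = comp[v], b = comp[-v])
  fw <- vapply(cuts, function(ct) sum(W[ct$a, ct$b, drop = FALSE]), numeric(1))
  list(cut = cuts[[which.min(fw)]], min_full_weight = min(fw))
}

#' CLICK-style graph clustering
#'
#' Clusters samples on a similarity graph. Pairwise similarities (Pearson
#' correlation of preprocessed marker vectors by default) are modeled as a
#' two-component normal mixture — same-cluster "mates" versus "non-mates" —
#' fitted by EM. Each pair gets the log-likelihood-ratio weight
#' `w = log[p phi_mates(s) / ((1-p) phi_non(s))]`; edges with `w <= 0` are
#' dropped. Connected components are split recursively along global
#' minimum-weight cuts until each component is a kernel: every cut has
#' positive total weight (counting the negative weights of absent edges) and
#' the mean within-component similarity clears the homogeneity threshold.
#' Leftover singletons are adopted by the most similar kernel when similar
#' enough, kernels with near-identical centroids are merged, and whatever
#' remains is UNCLASSIFIED (`NA` labels).
#'
#' When the EM mixture fails to separate (e.g. near-identical samples), the
#' algorithm falls back to a fixed similarity cutoff one pooled-sd above the
#' pooled mean and flags this in the provenance.
#'
#' @param cohort a preprocessed [cohort_matrix()] with >= 3 markers.
#' @param params a [click_params()].
#' @return A [clustering()] (labels `NA` for unclassified samples). The
#'   provenance `params` records the realized kernel count and whether the
#'   EM fallback was used.
#' @export
click_cluster <- function(cohort, params = click_params()) {
  stopifnot(inherits(params, "click_params"))
  X <- cohort$markers
  n <- nrow(X)
  if (ncol(X) < 3) stop("need >= 3 markers for pairwise similarity")
  if (n < 2) stop("need at least 2 samples")
  mk <- min(params$min_kernel, n)  # tiny inputs: whole data may be a kernel

  S <- if (params$similarity == "pearson") .row_cor(X) else -as.matrix(stats::dist(X))
  sv <- S[upper.tri(S)]
  fit <- .sim_mixture_em(sv, params$em_max_iter, params$em_tol)
  fallback <- is.null(fit)
  if (fallback) {
    if (!is.finite(stats::sd(sv)) || stats::sd(sv) < 1e-8) {
      # essentially identical similarities (e.g. duplicated samples):
      # everything is mates
      cutoff <- min(sv) - 1
    } else {
      # top quintile of similarities as candidate mates, mirroring the EM
      # initialization
      cutoff <- stats::quantile(sv, 0.8, names = FALSE)
    }
    W <- S - cutoff
    crossing <- cutoff
  } else {
    W <- .mixture_weights(S, fit)
    # similarity where mates and non-mates are equally likely (w = 0);
    # the self-calibrating default for the homogeneity/adoption/merge gates
    crossing <- (fit$mu1 + fit$mu0) / 2 +
      fit$sd1^2 * log((1 - fit$p) / fit$p) / (fit$mu1 - fit$mu0)
    crossing <- min(max(crossing, fit$mu0), fit$mu1)
  }
  diag(W) <- 0
  thr_homog <- if (is.null(params$homogeneity)) crossing else params$homogeneity
  thr_adopt <- if (is.null(params$adoption)) crossing else params$adoption
  thr_merge <- if (is.null(params$merge)) crossing else params$merge

  # kernel phase on an index pool: recursive splitting along the most
  # negative candidate cut until every surviving component is a kernel.
  # Re-componentization per split is unnecessary: a disconnected set has a
  # zero-edge (negative full weight) cut, which the candidates expose.
  find_kernels <- function(pool) {
    kernels <- list()
    singles <- integer(0)
    stack <- .pos_components(W, pool)
    while (length(stack)) {
      comp <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (length(comp) < mk) { singles <- c(singles, comp); next }
      cc <- .component_cuts(W, comp, params$exact_cut_max)
      Ssub <- S[comp, comp, drop = FALSE]
      homog <- mean(Ssub[upper.tri(Ssub)])
      if (cc$min_full_weight > 0 && homog >= thr_homog) {
        kernels[[length(kernels) + 1L]] <- comp
      } else if (length(cc$cut$a) == 1 && length(comp) > 2 * params$exact_cut_max) {
        # screening: batch-peel the weakest vertices of large components
        # instead of one Stoer-Wagner-sized step per vertex
        Wpos <- W[comp, comp, drop = FALSE]
        Wpos[Wpos < 0] <- 0
        deg <- rowSums(Wpos)
        npeel <- max(1L, length(comp) %/% 50L)
        peel <- order(deg)[seq_len(npeel)]
        singles <- c(singles, comp[peel])
        stack <- c(stack, list(comp[-peel]))
      } else {
        stack <- c(stack, list(cc$cut$a), list(cc$cut$b))
      }
    }
    keep <- lengths(kernels) >= mk
    singles <- c(singles, unlist(kernels[!keep], use.names = FALSE))
    list(kernels = kernels[keep], singles = singles)
  }

  # adoption, iterated to a fixpoint: each leftover sample joins the kernel
  # with the highest mean similarity to its members, if similar enough
  adopt <- function(kernels, singles) {
    if (length(kernels) && length(singles)) {
      for (round in seq_len(20)) {
        if (!length(singles)) break
        ms <- vapply(kernels, function(kn)
          rowMeans(S[singles, kn, drop = FALSE]), numeric(length(singles)))
        ms <- matrix(ms, nrow = length(singles))
        best <- max.col(ms, ties.method = "first")
        ok <- ms[cbind(seq_along(singles), best)] >= thr_adopt
        if (!any(ok)) break
        for (k in unique(best[ok]))
          kernels[[k]] <- c(kernels[[k]], singles[ok & best == k])
        singles <- singles[!ok]
      }
    }
    list(kernels = kernels, singles = singles)
  }

  # alternate kernel finding on the leftover pool with adoption until the
  # pool stops shrinking (unlucky recursion paths can shatter a true cluster
  # on the first pass; a second pass over its members recovers it)
  kernels <- list()
  singles <- seq_len(n)
  for (round in seq_len(5)) {
    kf <- find_kernels(singles)
    if (!length(kf$kernels) && round > 1) break
    kernels <- c(kernels, kf$kernels)
    ad <- adopt(kernels, kf$singles)
    kernels <- ad$kernels
    if (length(ad$singles) >= length(singles) || !length(ad$singles)) {
      singles <- ad$singles
      break
    }
    singles <- ad$singles
  }

  # merge kernels with near-identical centroids
  if (length(kernels) > 1) {
    repeat {
      cen <- t(vapply(kernels, function(kn)
        colMeans(X[kn, , drop = FALSE]), numeric(ncol(X))))
      if (params$similarity == "pearson") {
        Csim <- suppressWarnings(stats::cor(t(cen)))
        Csim[!is.finite(Csim)] <- -1
      } else Csim <- -as.matrix(stats::dist(cen))
      diag(Csim) <- -Inf
      if (max(Csim) <= thr_merge) break
      ij <- which(Csim == max(Csim), arr.ind = TRUE)[1, ]
      kernels[[ij[1]]] <- c(kernels[[ij[1]]], kernels[[ij[2]]])
      kernels[[ij[2]]] <- NULL
      if (length(kernels) == 1) break
    }
  }

  # merged kernels are broader; give remaining singletons a final chance
  ad <- adopt(kernels, singles)
  kernels <- ad$kernels
  singles <- ad$singles

  # final reassignment polish: every sample moves to the cluster whose
  # centroid it is most similar to (or back to the unclassified pool when
  # nothing clears the adoption gate); clusters falling below the minimum
  # kernel size dissolve. Corrects members misplaced by selection effects
  # during the kernel phase.
  if (length(kernels) > 1) {
    # survival gate for the polish: a member of a genuine mates-cluster has
    # centroid similarity ~ sqrt(mates mean); noise cliques sit just above
    # the pairwise crossing point and dissolve under this gate
    thr_refine <- if (!fallback && params$similarity == "pearson" &&
                      is.null(params$adoption))
      0.8 * sqrt(max(fit$mu1, 0.01)) else thr_adopt
    lab <- rep(NA_integer_, n)
    for (k in seq_along(kernels)) lab[kernels[[k]]] <- k
    for (round in seq_len(10)) {
      ks <- sort(unique(lab[!is.na(lab)]))
      if (length(ks) < 2) break
      cen <- t(vapply(ks, function(k)
        colMeans(X[which(lab == k), , drop = FALSE]), numeric(ncol(X))))
      csim <- if (params$similarity == "pearson")
        suppressWarnings(stats::cor(t(X), t(cen)))
      else -sqrt(outer(rowSums(X^2), rowSums(cen^2), "+") -
                   2 * tcrossprod(X, cen))
      csim[!is.finite(csim)] <- -1
      best <- max.col(csim, ties.method = "first")
      bsim <- csim[cbind(seq_len(n), best)]
      new_lab <- ifelse(bsim >= thr_refine, ks[best], NA_integer_)
      sz <- table(factor(new_lab, levels = ks))
      new_lab[new_lab %in% as.integer(names(sz)[sz < mk])] <- NA_integer_
      if (identical(new_lab, lab)) break
      lab <- new_lab
    }
    kernels <- lapply(sort(unique(lab[!is.na(lab)])), function(k) which(lab == k))
    singles <- which(is.na(lab))
  }

  labels <- rep(NA_integer_, n)
  for (k in seq_along(kernels)) labels[kernels[[k]]] <- k
  clustering(cohort$sample_ids, labels, "click",
             params = list(click = unclass(params), fallback = fallback,
                           realized_k = length(kernels)),
             seed = params$seed)
}
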