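# Single-hidden-layer feed-forward classifier (tanh hidden units, softmax
# output) trained by L-BFGS-B on L2-penalised multinomial cross-entropy.
# Small and deterministic; stands in for proprietary ANN tooling.
.ffnn_fit <- function(X, y, hidden, seed, maxit = 300, decay = 1e-4) {
  n <- nrow(X); P <- ncol(X); K <- max(y)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1
  npar1 <- (P + 1) * hidden
  npar2 <- (hidden + 1) * K
  unpack <- function(th) list(
    W1 = matrix(th[seq_len(npar1)], P + 1, hidden),
    W2 = matrix(th[npar1 + seq_len(npar2)], hidden + 1, K))
  fwd <- function(w) {
    H <- tanh(cbind(1, X) %*% w$W1)
    Z <- cbind(1, H) %*% w$W2
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    list(H = H, Pr = E / rowSums(E))
  }
  fn <- function(th) {
    w <- unpack(th)
    f <- fwd(w)
    -sum(Y * log(pmax(f$Pr, 1e-12))) / n + decay * sum(th^2)
  }
  gr <- function(th) {
    w <- unpack(th)
    f <- fwd(w)
    dZ <- (f$Pr - Y) / n
    gW2 <- crossprod(cbind(1, f$H), dZ)
    dH <- (dZ %*% t(w$W2[-1, , drop = FALSE])) * (1 - f$H^2)
    gW1 <- crossprod(cbind(1, X), dH)
    c(as.vector(gW1), as.vector(gW2)) + 2 * decay * th
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  th0 <- stats::rnorm(npar1 + npar2, 0, 0.2)
  opt <- stats::optim(th0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  unpack(opt$par)
}

.ffnn_predict <- function(w, X) {
  H <- tanh(cbind(1, X) %*% w$W1)
  Z <- cbind(1, H) %*% w$W2
  max.col(Z, ties.method = "first")
}

#' Train a projector from training-cohort cluster labels
#'
#' Fits a classifier on the preprocessed training matrix and its cluster
#' labels so validation-cohort samples can be assigned to the same
#' training-derived clusters. Unclassified training samples are excluded from
#' fitting. The classifier is a single-hidden-layer feed-forward network
#' (hidden size `2 * P` by default) or a deterministic nearest-centroid
#' model; with fewer than 2 clusters of size >= 2 the nearest-centroid
#' (or constant) form is forced.
#'
#' @param cohort the preprocessed training [cohort_matrix()].
#' @param cl the training [clustering()].
#' @param method `"ffnn"` or `"centroid"`.
#' @param hidden hidden layer size (default `2 * ncol`).
#' @param seed integer seed (network initialization).
#' @param maxit optimizer iteration cap.
#' @return An object of class `projector` with the fitted model, the marker
#'   schema, the training K and the re-substitution accuracy.
#' @export
train_projector <- function(cohort, cl, method = c("ffnn", "centroid"),
                            hidden = NULL, seed = 1L, maxit = 300) {
  method <- match.arg(method)
  lab <- cl$labels[cohort$sample_ids]
  keep <- !is.na(lab)
  X <- cohort$markers[keep, , drop = FALSE]
  y <- lab[keep]
  classes <- sort(unique(y))
  if (length(classes) < 2 || sum(table(y) >= 2) < 2) {
    if (length(classes) == 0) stop("no classified training samples")
    model <- list(type = "constant", label = classes[1])
    if (length(classes) > 1) {
      cen <- t(vapply(classes, function(k)
        colMeans(X[y == k, , drop = FALSE]), numeric(ncol(X))))
      model <- list(type = "centroid", centroids = cen, classes = classes)
    }
  } else if (method == "centroid") {
    cen <- t(vapply(classes, function(k)
      colMeans(X[y == k, , drop = FALSE]), numeric(ncol(X))))
    model <- list(type = "centroid", centroids = cen, classes = classes)
  } else {
    if (is.null(hidden)) hidden <- 2 * ncol(X)
    yd <- match(y, classes)
    w <- .ffnn_fit(X, yd, hidden, seed, maxit = maxit)
    model <- list(type = "ffnn", weights = w, classes = classes)
  }
  pj <- structure(list(model = model, marker_names = cohort$marker_names,
                       k = length(classes), seed = seed, method = method),
                  class = "projector")
  pred <- .projector_predict(pj, X)
  pj$resubstitution_accuracy <- mean(pred == y)
  pj
}

.projector_predict <- function(pj, X) {
  m <- pj$model
  switch(m$type,
    constant = rep(m$label, nrow(X)),
    centroid = {
      d <- outer(rowSums(X^2), rowSums(m$centroids^2), "+") -
        2 * tcrossprod(X, m$centroids)
      m$classes[max.col(-d, ties.method = "first")]
    },
    ffnn = m$classes[.ffnn_predict(m$weights, X)])
}

#' Project a validation cohort onto training clusters
#'
#' Assigns every sample of the (identically preprocessed) validation cohort a
#' training cluster label, so cluster identities are shared across cohorts
#' and "equivalent clusters" are label-identical.
#'
#' @param pj a [projector()][train_projector()].
#' @param cohort the preprocessed validation [cohort_matrix()]; its marker
#'   set and order must match the training cohort.
#' @return A [clustering()] carrying training labels.
#' @export
project <- function(pj, cohort) {
  stopifnot(inherits(pj, "projector"))
  if (!identical(cohort$marker_names, pj$marker_names)) {
    d1 <- setdiff(pj$marker_names, cohort$marker_names)
    d2 <- setdiff(cohort$marker_names, pj$marker_names)
    stop(sprintf("marker sets differ; training-only: {%s}, validation-only: {%s}",
                 paste(d1, collapse = ","), paste(d2, collapse = ",")))
  }
  pred <- .projector_predict(pj, cohort$markers)
  clustering(cohort$sample_ids, pred, paste0("projected_", pj$model$type),
             params = list(k_train = pj$k), seed = pj$seed, compact = FALSE)
}
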