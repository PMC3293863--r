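# RNG bookkeeping: functions that take a `seed` argument restore the caller's
# RNG state on exit, so seeded package calls do not disturb user scripts.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples.
#' 1 means identical partitions (up to label permutation), 0 is the expected
#' value under independent random labelings. Samples with `NA` in either
#' labeling (e.g. unclassified) are dropped from the comparison.
#'
#' @param a,b label vectors of equal length.
#' @return The adjusted Rand index, a number <= 1.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) return(NA_real_)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  expected <- si * sj / n2
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

# Pairwise Pearson correlation between the rows of X (samples), computed as a
# crossproduct of row-standardized values. Rows must be non-constant.
.row_cor <- function(X) {
  n <- nrow(X); P <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  ss <- sqrt(rowSums(Xc^2))
  if (any(ss == 0)) stop("sample with constant marker vector: correlation undefined")
  Xs <- Xc / ss
  S <- tcrossprod(Xs)
  S[S > 1] <- 1; S[S < -1] <- -1
  S
}

# Pearson correlation of two vectors with a helpful degenerate-input error.
.safe_cor <- function(x, y, what = "vector") {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop(sprintf("constant %s: correlation undefined", what))
  stats::cor(x, y)
}
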