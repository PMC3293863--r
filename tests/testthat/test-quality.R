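test_that("single-cluster convention: S_A = 0, diff = H_A", {
  co <- gaussian_cohort(n = 20, P = 5, seed = 1)
  cl <- clustering(co$sample_ids, rep(1, 20))
  q <- cluster_quality(co, cl)
  expect_equal(q$S_A, 0)
  expect_equal(q$diff, q$H_A)
})

test_that("perfect antipodal construction gives H = 1, S = -1", {
  cen <- c(1, 2, 3)
  m <- rbind(cen, cen, rev(cen), rev(cen))
  co <- cohort_matrix(paste0("s", 1:4), c(30, 40, 50, 60), m)
  cl <- clustering(co$sample_ids, c(1, 1, 2, 2))
  q <- cluster_quality(co, cl)
  expect_equal(q$H_A, 1)
  expect_equal(q$S_A, -1)
  expect_equal(q$diff, 2)
})

test_that("quality matches the double-loop oracle on random instances", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    X <- matrix(rnorm(n * 5), n, 5)
    co <- cohort_matrix(paste0("s", seq_len(n)), runif(n, 20, 80), X)
    lab <- kmeans_cluster(co, 3, seed = rep)$labels
    q <- cluster_quality(co, clustering(co$sample_ids, lab))
    o <- quality_oracle(X, lab)
    expect_equal(q$H_A, o$H_A, tolerance = 1e-10)
    expect_equal(q$S_A, o$S_A, tolerance = 1e-10)
  }
})

test_that("quality is invariant to relabeling, sample order and NA samples", {
  co <- gaussian_cohort(n = 30, P = 6, seed = 4)
  lab <- rep(1:3, 10)
  q1 <- cluster_quality(co, clustering(co$sample_ids, lab))
  q2 <- cluster_quality(co, clustering(co$sample_ids, 4 - lab))
  expect_equal(q1$diff, q2$diff, tolerance = 1e-12)
  perm <- sample(30)
  co_p <- cohort_subset(co, perm)
  q3 <- cluster_quality(co_p, clustering(co$sample_ids, lab))
  expect_equal(q1$diff, q3$diff, tolerance = 1e-12)
  # unclassified samples are excluded
  lab_na <- lab; lab_na[1:5] <- NA
  q4 <- cluster_quality(co, clustering(co$sample_ids, lab_na))
  o4 <- quality_oracle(co$markers, lab_na)
  expect_equal(q4$diff, o4$diff, tolerance = 1e-10)
})

test_that("degenerate constant centroids are reported", {
  m <- cbind(c(1, 1, 2, 3), c(1, 1, 2, 4), c(1, 1, 3, 5))
  co <- cohort_matrix(paste0("s", 1:4), c(30, 40, 50, 60), m)
  cl <- clustering(co$sample_ids, c(1, 1, 2, 2))
  expect_error(cluster_quality(co, cl), "cluster 1")
})

test_that("resampling: no dropout with one rep reproduces the full run", {
  spec <- plain_spec(n_train = 120, K = 3, separation = 6, seed = 5)
  pair <- generate_cohort_pair(spec)
  qs <- quality_resample(pair$train, "zscore", "kmeans", k = 3,
                         frac = 0, n_reps = 1, seed = 17)
  expect_equal(qs$mean_diff, qs$diff)
  expect_equal(qs$mean_K, qs$K)
})

test_that("resampling is seeded and stable on easy problems", {
  spec <- plain_spec(n_train = 200, K = 3, separation = 6, seed = 6)
  pair <- generate_cohort_pair(spec)
  a <- quality_resample(pair$train, "zscore", "kmeans", k = 3,
                        n_reps = 10, seed = 2)
  b <- quality_resample(pair$train, "zscore", "kmeans", k = 3,
                        n_reps = 10, seed = 2)
  expect_identical(a$resampled, b$resampled)
  expect_lt(a$sd_diff, 0.05)
  expect_equal(nrow(a$resampled), 10)
})

test_that("quality comparison reproduces the closed-form Student's t", {
  x <- c(0.54, 0.55, 0.56, 0.55, 0.54, 0.56, 0.55, 0.54, 0.56, 0.55)
  y <- x - 0.5
  r <- compare_quality(x, y)
  sp2 <- (9 * var(x) + 9 * var(y)) / 18
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 10))
  expect_equal(r$t, t_manual, tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-abs(t_manual), 18), tolerance = 1e-12)
  expect_lt(r$p, 1e-6)

  same <- compare_quality(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  const <- compare_quality(rep(0.5, 5), rep(0.5, 5))
  expect_true(const$degenerate)
  expect_equal(const$p, 1)
  shifted <- compare_quality(rep(0.5, 5), rep(0.4, 5))
  expect_equal(shifted$p, 0)
})

test_that("equal-location resampled lists rarely reject (type I control)", {
  set.seed(8)
  rejections <- 0
  for (rep in 1:100) {
    a <- rnorm(10, 0.5, 0.01)
    b <- rnorm(10, 0.5, 0.01)
    if (compare_quality(a, b)$p <= 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 10)
})

test_that("quality difference increases with planted separation", {
  diffs <- vapply(c(1, 3, 6), function(sep) {
    spec <- plain_spec(n_train = 150, K = 3, separation = sep, seed = 9)
    pair <- generate_cohort_pair(spec)
    pp <- preprocess(pair$train, "zscore")
    cluster_quality(pp$cohort,
                    kmeans_cluster(pp$cohort, 3, seed = 1))$diff
  }, numeric(1))
  expect_true(all(diff(diffs) >= 0))
})
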