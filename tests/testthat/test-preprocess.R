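test_that("sample skewness matches the adjusted moment formula", {
  expect_equal(sample_skewness(c(1, 2, 3)), 0)
  # independent evaluation of m3 / m2^1.5 with the small-sample factor
  v <- c(1, 1, 1, 10)
  m <- mean(v)
  g1 <- mean((v - m)^3) / mean((v - m)^2)^1.5
  expect_equal(sample_skewness(v), g1 * sqrt(4 * 3) / 2)
  expect_error(sample_skewness(c(5, 5, 5)), "zero variance")
  expect_error(sample_skewness(c(1, 2)), "at least 3")
})

test_that("normal transform logs only markers outside the normal band", {
  co <- gaussian_cohort(n = 500, P = 4, seed = 2)
  nt <- normal_transform(co)
  expect_identical(nt$cohort$markers, co$markers)
  expect_length(nt$transformed, 0)

  set.seed(3)
  m <- cbind(exp(rnorm(2000, 0, 1)), rnorm(2000, 5, 1))
  colnames(m) <- c("lognorm", "norm")
  co <- cohort_matrix(paste0("s", 1:2000), runif(2000, 20, 80), m)
  nt <- normal_transform(co)
  expect_identical(nt$transformed, "lognorm")
  expect_lte(abs(sample_skewness(nt$cohort$markers[, "lognorm"])), 1)

  m[1, 1] <- 0
  co0 <- cohort_matrix(paste0("s", 1:2000), runif(2000, 20, 80), m)
  expect_error(normal_transform(co0), "lognorm")
})

test_that("normal-transform gate agrees with brute-force skewness", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 200
    m <- cbind(rnorm(n), exp(rnorm(n)), rgamma(n, shape = 1),
               runif(n), exp(rnorm(n, 0, 2)) + 0.01)
    co <- cohort_matrix(paste0("s", 1:n), runif(n, 20, 80), m)
    nt <- normal_transform(co)
    brute <- co$marker_names[vapply(seq_len(ncol(m)), function(j) {
      v <- m[, j]; mu <- mean(v)
      g1 <- mean((v - mu)^3) / mean((v - mu)^2)^1.5
      abs(g1 * sqrt(n * (n - 1)) / (n - 2)) > 1
    }, logical(1))]
    expect_identical(nt$transformed, brute)
  }
})

test_that("z-score normalization standardizes and round-trips", {
  co <- cohort_matrix(c("a", "b", "c"), c(30, 40, 50), cbind(x = c(1, 2, 3)))
  zs <- zscore_normalize(co)
  expect_equal(unname(zs$cohort$markers[, 1]), c(-1, 0, 1))

  co <- gaussian_cohort(n = 80, P = 6, seed = 4)
  co$markers <- sweep(sweep(co$markers, 2, c(1, 10, 100, 0.1, 5, 50), "*"),
                      2, c(0, 5, -3, 2, 0, 100), "+")
  zs <- zscore_normalize(cohort_matrix(co$sample_ids, co$ages, co$markers))
  expect_true(all(abs(colMeans(zs$cohort$markers)) < 1e-10))
  expect_true(all(abs(apply(zs$cohort$markers, 2, sd) - 1) < 1e-10))
  # idempotence
  zs2 <- zscore_normalize(zs$cohort)
  expect_equal(zs2$cohort$markers, zs$cohort$markers, tolerance = 1e-10)
  # manual undo recovers the input
  undo <- sweep(sweep(zs$cohort$markers, 2, zs$scale, "*"), 2, zs$center, "+")
  expect_equal(undo, co$markers, tolerance = 1e-8)

  bad <- cohort_matrix(c("a", "b"), c(25, 30), cbind(flat = c(1, 1)))
  expect_error(zscore_normalize(bad), "zero-variance")
})

test_that("age adjustment kills the linear age component and keeps means", {
  set.seed(6)
  n <- 2000
  ages <- runif(n, 20, 85)
  m <- cbind(planted = 0.5 * ages + rnorm(n, 0, 1),
             null = rnorm(n, 10, 2))
  co <- cohort_matrix(paste0("s", 1:n), ages, m)
  aa <- age_adjust(co)
  expect_true(aa$model$adjusted[1])
  expect_false(aa$model$adjusted[2])
  expect_identical(co$markers[, "null"], aa$cohort$markers[, "null"])
  expect_lt(abs(cor(aa$cohort$markers[, "planted"], ages)), 0.05)
  expect_lt(abs(mean(aa$cohort$markers[, "planted"]) - mean(m[, "planted"])),
            1e-10)
  # exact orthogonality on the fitting sample
  expect_lt(abs(cor(aa$cohort$markers[, "planted"], ages)), 1e-10)
})

test_that("a perfectly age-determined marker becomes its mean", {
  ages <- seq(20, 70, length.out = 100)
  co <- cohort_matrix(paste0("s", 1:100), ages, cbind(v = 2 * ages))
  aa <- age_adjust(co)
  expect_equal(unname(aa$cohort$markers[, "v"]), rep(mean(2 * ages), 100),
               tolerance = 1e-10)
  flat <- cohort_matrix(c("a", "b", "c"), c(30, 30, 30),
                        cbind(v = c(1, 2, 3)))
  expect_error(age_adjust(flat), "constant age")
})

test_that("preprocess variants compose as documented", {
  spec <- plain_spec(n_train = 150, K = 2, seed = 8)
  pair <- generate_cohort_pair(spec)
  raw <- preprocess(pair$train, "raw")
  expect_identical(raw$cohort$markers, pair$train$markers)

  # zero age slopes everywhere: age adjustment is vacuous
  aaz <- preprocess(pair$train, "age_adjust_zscore")
  zs <- preprocess(pair$train, "zscore")
  expect_equal(aaz$cohort$markers, zs$cohort$markers, tolerance = 1e-10)

  # frozen-parameter application on the same cohort reproduces the refit
  frozen <- apply_preprocess(zs, pair$train)
  expect_equal(frozen$cohort$markers, zs$cohort$markers, tolerance = 1e-12)

  # aggregate mode logs skewed markers before standardizing
  spec2 <- generator_spec(n_train = 400, n_valid = 10, seed = 9)
  pair2 <- generate_cohort_pair(spec2)
  agg <- preprocess(pair2$train, "zscore", aggregate_transforms = TRUE)
  expect_gt(length(agg$record$log_markers), 0)
  expect_true(all(abs(colMeans(agg$cohort$markers)) < 1e-10))
})

test_that("missing values follow the complete-case default", {
  spec <- generator_spec(n_train = 200, n_valid = 10, missing_rate = 0.01,
                         seed = 12)
  pair <- generate_cohort_pair(spec)
  pp <- preprocess(pair$train, "zscore")
  expect_false(any(is.na(pp$cohort$markers)))
  expect_gt(length(pp$dropped), 0)
  expect_equal(length(pp$cohort$sample_ids) + length(pp$dropped), 200)
  imp <- preprocess(pair$train, "zscore", missing = "impute")
  expect_equal(length(imp$cohort$sample_ids), 200)
})
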