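test_that("hypergeometric boundary cases", {
  expect_equal(hypergeom_pvalue(10, 5, 4, 0), 1)
  expect_equal(hypergeom_pvalue(10, 5, 10, 5), 1)
  expect_error(hypergeom_pvalue(10, 5, 4, 5), "inconsistent")
  expect_error(hypergeom_pvalue(10, 12, 4, 2), "inconsistent")
})

test_that("hypergeometric tail matches brute-force enumeration", {
  # exhaustive draws at a handful of nontrivial corners
  expect_equal(hypergeom_pvalue(10, 5, 4, 4), hypergeom_enum(10, 5, 4, 4),
               tolerance = 1e-12)
  for (tup in list(c(8, 3, 4, 2), c(9, 6, 3, 1), c(7, 2, 5, 2),
                   c(12, 6, 6, 4))) {
    expect_equal(hypergeom_pvalue(tup[1], tup[2], tup[3], tup[4]),
                 hypergeom_enum(tup[1], tup[2], tup[3], tup[4]),
                 tolerance = 1e-12)
  }
})

test_that("p is non-increasing in k_in and factor crosses 1 with frequency", {
  N <- 60; K <- 20; n <- 15
  ps <- vapply(0:15, function(k) hypergeom_pvalue(N, K, n, k), numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  for (k in 0:15) {
    f <- (k / n) / (K / N)
    expect_identical(f > 1, k / n > K / N)
  }
})

test_that("traits below the positives gate are not tested", {
  set.seed(4)
  ids <- paste0("s", 1:200)
  cl <- clustering(ids, rep(1:4, each = 50))
  tt <- trait_table(ids, cbind(rare = rbinom(200, 1, 0.05) * 0 +
                                 c(rep(1, 10), rep(0, 190)),
                               common = rbinom(200, 1, 0.3)))
  rec <- enrich_clusters(cl, tt)
  expect_false("rare" %in% rec$trait)
  expect_true("common" %in% rec$trait)
  expect_equal(sort(unique(rec$cluster[rec$trait == "common"])), 1:4)
})

test_that("unknown trait status samples are excluded per trait", {
  ids <- paste0("s", 1:100)
  cl <- clustering(ids, rep(1:2, each = 50))
  v <- c(rep(1, 40), rep(0, 50), rep(NA, 10))
  tt <- trait_table(ids, cbind(t1 = v))
  rec <- enrich_clusters(cl, tt)
  expect_true(all(rec$N == 90))
  expect_true(all(rec$K_trait == 40))
})

test_that("a planted association is detected with a large factor", {
  set.seed(5)
  n <- 2000
  lab <- sample(1:5, n, TRUE)
  p <- plogis(qlogis(0.1) + log(8) * (lab == 2))
  tr <- rbinom(n, 1, p)
  cl <- clustering(paste0("s", 1:n), lab)
  tt <- trait_table(paste0("s", 1:n), cbind(planted = tr))
  rec <- enrich_clusters(cl, tt)
  hit <- rec[rec$cluster == 2 & rec$trait == "planted", ]
  expect_true(hit$significant)
  expect_gt(hit$factor, 2)
})

test_that("null traits are controlled at the per-test level", {
  set.seed(6)
  tests <- 0; rejects <- 0
  for (rep in 1:50) {
    lab <- sample(1:5, 2000, TRUE)
    tr <- rbinom(2000, 1, 0.1)
    cl <- clustering(paste0("s", 1:2000), lab)
    tt <- trait_table(paste0("s", 1:2000), cbind(t1 = tr))
    rec <- enrich_clusters(cl, tt)
    tests <- tests + nrow(rec)
    rejects <- rejects + sum(rec$significant)
  }
  expect_lte(rejects / tests, 0.07)
})

test_that("Benjamini-Hochberg flagging is available", {
  set.seed(7)
  lab <- rep(1:10, each = 40)
  tr <- rbinom(400, 1, 0.15)
  cl <- clustering(paste0("s", 1:400), lab)
  tt <- trait_table(paste0("s", 1:400), cbind(t1 = tr))
  raw <- enrich_clusters(cl, tt)
  bh <- enrich_clusters(cl, tt, bh = TRUE)
  expect_lte(sum(bh$significant), sum(raw$significant))
})

test_that("validation accounting: self, disjoint and constructed cases", {
  rec <- function(cluster, trait, p, factor, sig = TRUE)
    data.frame(cluster = cluster, trait = trait, N = 100, K_trait = 30,
               n_cluster = 20, k_in = 10, p = p, factor = factor,
               significant = sig)
  a <- rbind(rec(1, "t1", 1e-5, 3), rec(2, "t2", 1e-4, 2),
             rec(3, "t1", 0.2, 1.1, sig = FALSE))
  self <- validate_enrichments(a, a)
  expect_equal(self$valid, 2)
  expect_equal(self$total_train, 2)
  expect_equal(self$validated_clusters, self$enriched_clusters)
  expect_equal(self$ratio_total, "2/2")

  b <- rbind(rec(4, "t3", 1e-3, 5))
  disjoint <- validate_enrichments(a, b)
  expect_equal(disjoint$valid, 0)
  expect_equal(disjoint$validated_clusters, 0)
  expect_true(is.na(disjoint$pipeline_factor))

  # four valid enrichments with validation factors 9, 6, 3, 1 in p-order:
  # the pipeline factor averages the three most significant
  tr4 <- rbind(rec(1, "a", 1e-8, 2), rec(2, "b", 1e-7, 2),
               rec(3, "c", 1e-6, 2), rec(4, "d", 1e-5, 2))
  va4 <- rbind(rec(1, "a", 1e-9, 9), rec(2, "b", 1e-8, 6),
               rec(3, "c", 1e-7, 3), rec(4, "d", 1e-6, 1))
  r4 <- validate_enrichments(tr4, va4)
  expect_equal(r4$pipeline_factor, mean(c(9, 6, 3)))
  expect_equal(r4$distinct_valid, 4)
})

test_that("mismatched id sets raise an error", {
  cl <- clustering(paste0("a", 1:10), rep(1:2, 5))
  tt <- trait_table(paste0("b", 1:10), cbind(t1 = rep(0:1, 5)))
  expect_error(enrich_clusters(cl, tt), "share no sample ids")
})
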