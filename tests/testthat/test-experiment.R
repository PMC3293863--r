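# Small synthetic spec shared by the experiment tests: fast but end-to-end.
tiny_gen <- function(seed = 1L)
  generator_spec(n_train = 150, n_valid = 150, n_markers = 12,
                 n_subgroups = 3, separation = 6,
                 skewed_markers = integer(0),
                 marker_scales = rep(c(1, 10, 100), 4),
                 marker_offsets = rep(0, 12),
                 age_slopes = rep(0, 12),
                 n_traits = 4,
                 planted_odds = data.frame(subgroup = 1:3, trait = 1:3,
                                           odds = 8),
                 seed = seed)

test_that("a one-cell grid produces one row per table", {
  dir <- withr::local_tempdir()
  cfg <- experiment_config(generator = tiny_gen(), variants = "zscore",
                           algorithms = "kmeans", default_k = 3,
                           resample_reps = 3, min_positives = 10,
                           projector = "centroid", seed = 2, out_dir = dir)
  res <- suppressMessages(run_experiment(cfg))
  expect_equal(nrow(res$quality_table), 1)
  expect_equal(nrow(res$validation_table), 1)
  expect_true(file.exists(file.path(dir, "quality_table.csv")))
  expect_true(file.exists(file.path(dir, "run_log.txt")))
})

test_that("invalid configs fail before any computation", {
  expect_error(experiment_config(generator = NULL, train_csv = "x.csv"),
               "all four")
  expect_error(experiment_config(generator = tiny_gen(),
                                 variants = character(0)),
               "at least one")
  expect_error(experiment_config(generator = tiny_gen(),
                                 algorithms = "kmeans"),
               "default_k")
  expect_error(
    experiment_config(train_csv = "a", train_traits_csv = "b",
                      valid_csv = "c", valid_traits_csv = "d"),
    "not found")
})

test_that("K flows from the graph clustering to k-means and the SOM", {
  cfg <- experiment_config(generator = tiny_gen(3), variants = "zscore",
                           algorithms = c("click", "kmeans", "som"),
                           resample_reps = 2, min_positives = 10,
                           projector = "centroid", seed = 3)
  res <- suppressMessages(run_experiment(cfg))
  qt <- res$quality_table
  k_click <- qt$K[qt$algorithm == "click"]
  expect_equal(res$cells[["zscore/kmeans"]]$quality$clustering$params$k,
               k_click)
  expect_lte(qt$K[qt$algorithm == "som"], k_click)
})

test_that("experiment reruns are bit-identical", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  mk <- function(dir) {
    cfg <- experiment_config(generator = tiny_gen(4),
                             variants = c("raw", "zscore"),
                             algorithms = c("click", "kmeans"),
                             resample_reps = 2, min_positives = 10,
                             projector = "centroid", seed = 5, out_dir = dir)
    suppressMessages(run_experiment(cfg))
  }
  mk(d1); mk(d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("validation-table invariants hold on experiment output", {
  cfg <- experiment_config(generator = tiny_gen(6), variants = "zscore",
                           algorithms = c("click", "kmeans"),
                           resample_reps = 2, min_positives = 10,
                           projector = "centroid", seed = 7)
  res <- suppressMessages(run_experiment(cfg))
  for (cn in names(res$cells)) {
    rpt <- res$cells[[cn]]$report
    expect_lte(rpt$valid, rpt$total_train)
    expect_lte(rpt$validated_clusters, rpt$enriched_clusters)
    expect_lte(rpt$distinct_valid, rpt$distinct_train)
  }
})

test_that("CSV-mode experiments run from files written by the generator", {
  dir <- withr::local_tempdir()
  pair <- generate_cohort_pair(tiny_gen(8))
  write_cohort_pair(pair, dir)
  cfg <- experiment_config(
    train_csv = file.path(dir, "train.csv"),
    train_traits_csv = file.path(dir, "train_traits.csv"),
    valid_csv = file.path(dir, "valid.csv"),
    valid_traits_csv = file.path(dir, "valid_traits.csv"),
    variants = "zscore", algorithms = "kmeans", default_k = 3,
    resample_reps = 2, min_positives = 10, projector = "centroid", seed = 9)
  res <- suppressMessages(run_experiment(cfg))
  expect_equal(nrow(res$quality_table), 1)
  expect_gte(res$quality_table$diff, 0)
})
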