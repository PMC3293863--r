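#' Configuration for a full experiment grid
#'
#' Describes one training/validation experiment: which pre-processing
#' variants and clustering algorithms to cross, the resampling, enrichment
#' and projector settings, and where the inputs come from (a synthetic
#' [generator_spec()] or CSV paths).
#'
#' @param generator a [generator_spec()] for synthetic mode, or `NULL` when
#'   reading CSVs.
#' @param train_csv,train_traits_csv,valid_csv,valid_traits_csv input paths
#'   (ignored in synthetic mode).
#' @param variants subset of [pipeline_variants()].
#' @param algorithms subset of `c("click", "kmeans", "som")`.
#' @param resample_frac,resample_reps dropout resampling settings.
#' @param alpha,min_positives enrichment settings.
#' @param projector `"ffnn"` or `"centroid"`.
#' @param click a [click_params()].
#' @param default_k cluster count for k-means/SOM when `"click"` is not in
#'   `algorithms` (otherwise K is taken from the CLICK run of the same
#'   variant).
#' @param aggregate_transforms chain pre-processing steps cumulatively (see
#'   [preprocess()]).
#' @param som_epochs,kmeans_restarts algorithm settings.
#' @param seed global seed; per-cell seeds are derived from it.
#' @param out_dir output directory for report CSVs, or `NULL` to skip
#'   writing.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(generator = NULL,
                              train_csv = NULL, train_traits_csv = NULL,
                              valid_csv = NULL, valid_traits_csv = NULL,
                              variants = pipeline_variants(),
                              algorithms = c("click", "kmeans", "som"),
                              resample_frac = 0.03, resample_reps = 10,
                              alpha = 0.05, min_positives = 30,
                              projector = c("ffnn", "centroid"),
                              click = click_params(), default_k = NULL,
                              aggregate_transforms = FALSE,
                              som_epochs = 50, kmeans_restarts = 10,
                              seed = 1L, out_dir = NULL) {
  projector <- match.arg(projector)
  if (!length(variants) || !length(algorithms))
    stop("need at least one variant and one algorithm")
  if (!all(variants %in% pipeline_variants()))
    stop("unknown pre-processing variant")
  if (!all(algorithms %in% c("click", "kmeans", "som")))
    stop("unknown algorithm")
  if (is.null(generator)) {
    paths <- c(train_csv, train_traits_csv, valid_csv, valid_traits_csv)
    if (length(paths) != 4)
      stop("either a generator spec or all four input CSV paths are required")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop(sprintf("input file(s) not found: %s", paste(missing, collapse = ", ")))
  }
  if (!"click" %in% algorithms && is.null(default_k) &&
      any(c("kmeans", "som") %in% algorithms))
    stop("default_k is required when the grid has no CLICK run to take K from")
  structure(list(generator = generator, train_csv = train_csv,
                 train_traits_csv = train_traits_csv, valid_csv = valid_csv,
                 valid_traits_csv = valid_traits_csv,
                 variants = variants, algorithms = algorithms,
                 resample_frac = resample_frac, resample_reps = resample_reps,
                 alpha = alpha, min_positives = min_positives,
                 projector = projector, click = click, default_k = default_k,
                 aggregate_transforms = aggregate_transforms,
                 som_epochs = som_epochs, kmeans_restarts = kmeans_restarts,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

# stable small per-cell seed offsets (variant x algorithm), below 2^31
.cell_seed <- function(seed, vi, ai) seed + 10000L * vi + 100L * ai

#' Run the full pre-processing x clustering experiment grid
#'
#' For every variant x algorithm cell: preprocess both cohorts, cluster the
#' training cohort, score it with dropout resampling, train a projector on
#' the full-data training clustering, project the validation cohort, run
#' trait enrichment on both cohorts and tally validated enrichments. K for
#' k-means and the SOM is taken from the realized K of the CLICK run under
#' the same variant (or `default_k`). Re-running with an identical config is
#' bit-identical.
#'
#' @param config an [experiment_config()].
#' @return A list of class `experiment_result`: `quality_table`,
#'   `validation_table`, `trait_grid`, `enrichment_records` (data.frames),
#'   `cells` (per-cell detail), `log` (character). When `config$out_dir` is
#'   set the tables are also written as CSVs plus a `run_log.txt`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  log <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }
  if (!is.null(config$generator)) {
    pair <- generate_cohort_pair(config$generator)
    note("synthetic cohorts: %d train / %d valid samples, seed %d",
         config$generator$n_train, config$generator$n_valid,
         config$generator$seed)
  } else {
    pair <- list(train = read_cohort_csv(config$train_csv),
                 train_traits = read_traits_csv(config$train_traits_csv),
                 valid = read_cohort_csv(config$valid_csv),
                 valid_traits = read_traits_csv(config$valid_traits_csv))
    note("loaded cohorts from CSV: %d train / %d valid samples",
         length(pair$train$sample_ids), length(pair$valid$sample_ids))
  }

  # order algorithms so CLICK runs first and can donate K to the others
  algs <- intersect(c("click", "kmeans", "som"), config$algorithms)
  qt <- vt <- er <- list()
  cells <- list()
  for (vi in seq_along(config$variants)) {
    variant <- config$variants[vi]
    click_k <- config$default_k
    for (ai in seq_along(algs)) {
      alg <- algs[ai]
      cell_seed <- .cell_seed(config$seed, vi, ai)
      k <- if (alg == "click") NULL else click_k
      qs <- quality_resample(pair$train, variant, alg, k = k,
                             frac = config$resample_frac,
                             n_reps = config$resample_reps,
                             seed = cell_seed, click = config$click,
                             aggregate_transforms = config$aggregate_transforms,
                             som_epochs = config$som_epochs,
                             kmeans_restarts = config$kmeans_restarts)
      if (alg == "click") {
        click_k <- qs$K
        note("%s/click realized K = %d (donated to kmeans/som)", variant, qs$K)
        if (click_k == 0) {
          # no kernels on this variant ("0 clusters" row in the reports);
          # downstream algorithms need some k
          click_k <- if (!is.null(config$default_k)) config$default_k else 2L
          note("%s/click found no clusters; kmeans/som fall back to k = %d",
               variant, click_k)
        }
      }
      train_cl <- qs$clustering
      train_pp <- qs$preprocess

      if (qs$K == 0) {
        # nothing to project or enrich for this cell
        qt[[length(qt) + 1L]] <- data.frame(
          variant = variant, algorithm = alg, K = 0L, diff = NA_real_,
          mean_K = qs$mean_K, sd_K = qs$sd_K,
          mean_diff = qs$mean_diff, sd_diff = qs$sd_diff,
          valid_K = NA_integer_, valid_diff = NA_real_)
        vt[[length(vt) + 1L]] <- data.frame(
          variant = variant, algorithm = alg,
          valid_enrichments = "-", distinct = "-",
          validated_clusters = "-", enrichment_factor = NA_real_)
        cells[[paste(variant, alg, sep = "/")]] <-
          list(quality = qs, valid_quality = NULL, projector = NULL,
               report = NULL, train_clustering = train_cl,
               valid_clustering = NULL)
        note("%s/%s: no clusters; cell reported empty", variant, alg)
        next
      }

      # validation side: refit the same pre-processing on the validation
      # cohort, then quality of the projected clustering
      valid_pp <- preprocess(pair$valid, variant,
                             aggregate_transforms = config$aggregate_transforms)
      if (length(train_pp$dropped) || length(valid_pp$dropped))
        note("%s/%s complete-case drop: %d train, %d valid", variant, alg,
             length(train_pp$dropped), length(valid_pp$dropped))
      pj <- train_projector(train_pp$cohort, train_cl,
                            method = config$projector, seed = cell_seed + 1L)
      valid_cl <- project(pj, valid_pp$cohort)
      vq <- cluster_quality(valid_pp$cohort, valid_cl)

      tr_rec <- enrich_clusters(train_cl, pair$train_traits,
                                alpha = config$alpha,
                                min_positives = config$min_positives)
      va_rec <- enrich_clusters(valid_cl, pair$valid_traits,
                                alpha = config$alpha,
                                min_positives = config$min_positives)
      rpt <- validate_enrichments(tr_rec, va_rec)

      qt[[length(qt) + 1L]] <- data.frame(
        variant = variant, algorithm = alg,
        K = qs$K, diff = qs$diff,
        mean_K = qs$mean_K, sd_K = qs$sd_K,
        mean_diff = qs$mean_diff, sd_diff = qs$sd_diff,
        valid_K = vq$K, valid_diff = vq$diff)
      vt[[length(vt) + 1L]] <- data.frame(
        variant = variant, algorithm = alg,
        valid_enrichments = rpt$ratio_total,
        distinct = rpt$ratio_distinct,
        validated_clusters = rpt$ratio_clusters,
        enrichment_factor = rpt$pipeline_factor)
      if (nrow(tr_rec)) {
        tr_rec$cohort <- "train"; va_rec$cohort <- "valid"
        both <- rbind(tr_rec, va_rec)
        both$variant <- variant; both$algorithm <- alg
        er[[length(er) + 1L]] <- both
      }
      cells[[paste(variant, alg, sep = "/")]] <-
        list(quality = qs, valid_quality = vq, projector = pj,
             report = rpt, train_clustering = train_cl,
             valid_clustering = valid_cl)
      note("%s/%s: K=%d diff=%.3f valid %s factor %.2f", variant, alg,
           qs$K, qs$diff, rpt$ratio_total, rpt$pipeline_factor)
    }
  }
  quality_table <- do.call(rbind, qt)
  validation_table <- do.call(rbind, vt)
  enrichment_records <- if (length(er)) do.call(rbind, er) else
    data.frame()

  # qualitative trait x pipeline grid of validated traits
  trait_grid <- NULL
  if (nrow(enrichment_records)) {
    traits <- sort(unique(enrichment_records$trait))
    cols <- lapply(names(cells), function(cn) {
      vv <- cells[[cn]]$report$valid_records
      if (is.null(vv)) return(rep("", length(traits)))
      ifelse(traits %in% unique(vv$trait), "Y", "")
    })
    trait_grid <- data.frame(trait = traits,
                             stats::setNames(cols, names(cells)),
                             check.names = FALSE)
  }

  out <- structure(list(quality_table = quality_table,
                        validation_table = validation_table,
                        trait_grid = trait_grid,
                        enrichment_records = enrichment_records,
                        cells = cells, log = log, config = config),
                   class = "experiment_result")
  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

#' Write an experiment result bundle as CSVs
#'
#' Emits `quality_table.csv`, `validation_table.csv`, `trait_grid.csv`,
#' `enrichment_records.csv` and `run_log.txt` into `dir`.
#'
#' @param result an `experiment_result` from [run_experiment()].
#' @param dir output directory (created if absent).
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$quality_table,
                   file.path(dir, "quality_table.csv"), row.names = FALSE)
  utils::write.csv(result$validation_table,
                   file.path(dir, "validation_table.csv"), row.names = FALSE)
  if (!is.null(result$trait_grid))
    utils::write.csv(result$trait_grid,
                     file.path(dir, "trait_grid.csv"), row.names = FALSE)
  utils::write.csv(result$enrichment_records,
                   file.path(dir, "enrichment_records.csv"),
                   row.names = FALSE)
  cfg <- result$config
  # path fields are machine-specific and would break bit-identical reruns
  drop_fields <- c("generator", "out_dir", "train_csv", "train_traits_csv",
                   "valid_csv", "valid_traits_csv")
  scalars <- Filter(function(x) is.atomic(x) && length(x) <= 8,
                    cfg[setdiff(names(cfg), drop_fields)])
  resolved <- c(
    "# resolved configuration",
    vapply(names(scalars), function(nm)
      sprintf("%s: %s", nm, paste(scalars[[nm]], collapse = ",")),
      character(1)),
    if (!is.null(cfg$generator))
      sprintf("generator_seed: %d", cfg$generator$seed))
  writeLines(c(resolved, "# log", result$log),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}
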