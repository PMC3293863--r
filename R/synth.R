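# Near-balanced +/-1 codewords (up to 6 subgroups x 10 informative markers)
# with pairwise Hamming distance >= 5; fixed so the default generator is
# fully deterministic.
.default_codewords <- rbind(
  c(-1, -1,  1,  1, -1,  1,  1, -1, -1, -1),
  c( 1, -1, -1,  1, -1, -1,  1,  1,  1,  1),
  c(-1, -1, -1, -1,  1,  1,  1,  1, -1,  1),
  c( 1, -1,  1,  1,  1, -1, -1, -1, -1,  1),
  c(-1,  1,  1, -1, -1,  1, -1, -1,  1,  1),
  c(-1,  1, -1,  1,  1, -1, -1,  1, -1, -1))

#' Specification for the synthetic cohort-pair generator
#'
#' Describes a generative process emulating an adult-male survey biomarker
#' panel: `n_subgroups` latent subgroups mixing in given proportions, each
#' marker built on a latent standardized scale as
#' `centroid[k, j] + age_slope_j * (age - midpoint age) + Normal(0, noise_sd)`,
#' mapped to heterogeneous observed units by `scale * g(latent) + offset`
#' where `g = exp` for right-skewed markers and the identity otherwise.
#' Binary traits are Bernoulli with
#' `logit(p) = logit(baseline) + log(OR)` for planted (subgroup, trait) pairs.
#'
#' The default centroid design places the subgroups on balanced
#' `+/- separation/2` codewords over the first 10 ("informative") markers with
#' pairwise Hamming distance >= 5, i.e. a per-marker between-subgroup gap of
#' `separation` (default `4 * noise_sd`) on at least 5 markers for every
#' subgroup pair.
#'
#' @param n_train,n_valid cohort sizes.
#' @param n_markers number of biomarkers (default 40).
#' @param n_subgroups number of latent subgroups K.
#' @param mixing_proportions simplex vector of length K.
#' @param separation per-marker between-subgroup mean gap on the informative
#'   markers, in latent (noise-sd) units.
#' @param centroid_matrix optional K x n_markers matrix of latent subgroup
#'   means; overrides the default codeword design.
#' @param noise_sd latent marker noise standard deviation.
#' @param skewed_markers indices of markers passed through `exp` (right-skewed
#'   on the observed scale).
#' @param marker_scales,marker_offsets per-marker affine map to observed units.
#' @param age_range two-element `[lo, hi]` in years; `lo >= 20`.
#' @param age_slopes per-marker latent slope per year of age.
#' @param n_traits number of binary traits (default 19).
#' @param baseline_prevalence per-trait baseline probability.
#' @param planted_odds data.frame with columns `subgroup`, `trait`, `odds`
#'   giving the planted odds ratios; `NULL` plants trait j in subgroup j
#'   (j = 1..K) at odds ratio 8.
#' @param missing_rate MCAR masking probability (default 0).
#' @param cohort_shift sd of a Normal perturbation added to the validation
#'   cohort's centroids, to probe robustness to cohort drift; default 0 (the
#'   two cohorts are i.i.d. draws from one process).
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_train = 1200, n_valid = 1200,
                           n_markers = 40, n_subgroups = 5,
                           mixing_proportions = NULL,
                           separation = 4, centroid_matrix = NULL,
                           noise_sd = 1,
                           skewed_markers = NULL,
                           marker_scales = NULL, marker_offsets = NULL,
                           age_range = c(20, 85), age_slopes = NULL,
                           n_traits = 19, baseline_prevalence = 0.1,
                           planted_odds = NULL,
                           missing_rate = 0, cohort_shift = 0, seed = 1L) {
  K <- n_subgroups
  if (is.null(mixing_proportions)) mixing_proportions <- rep(1 / K, K)
  if (n_train < 1 || n_valid < 1 || n_markers < 1 || K < 1)
    stop("counts must be positive")
  if (K > n_train) stop("more subgroups than training samples")
  if (length(mixing_proportions) != K ||
      abs(sum(mixing_proportions) - 1) > 1e-12 || any(mixing_proportions < 0))
    stop("mixing_proportions must be a simplex vector of length n_subgroups")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (age_range[1] < 20) stop("age_range lower bound must be >= 20")
  if (age_range[2] < age_range[1]) stop("invalid age_range")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate in [0, 1)")

  if (is.null(centroid_matrix)) {
    n_inf <- min(10L, n_markers)
    centroid_matrix <- matrix(0, K, n_markers)
    cw <- .default_codewords
    if (K > nrow(cw)) { # recycle with sign flips for K > 6
      cw <- rbind(cw, -cw)
      if (K > nrow(cw)) stop("default centroid design supports up to 12 subgroups")
    }
    centroid_matrix[, seq_len(n_inf)] <-
      (separation * noise_sd / 2) * cw[seq_len(K), seq_len(n_inf)]
  }
  centroid_matrix <- as.matrix(centroid_matrix)
  if (!all(dim(centroid_matrix) == c(K, n_markers)))
    stop("centroid_matrix must be n_subgroups x n_markers")

  if (is.null(skewed_markers))
    skewed_markers <- if (n_markers >= 40) 33:40 else integer(0)
  if (is.null(age_slopes)) {
    age_slopes <- numeric(n_markers)
    if (n_markers >= 22) age_slopes[11:22] <- 0.03
  }
  if (length(age_slopes) != n_markers) stop("age_slopes length mismatch")
  if (is.null(marker_scales)) {
    # heterogeneous observed units spanning ~3.5 decades, fixed arrangement
    marker_scales <- rep(c(0.5, 4, 30, 120, 1, 8, 250, 0.1, 15, 60),
                         length.out = n_markers)
  }
  if (is.null(marker_offsets)) {
    marker_offsets <- ifelse(seq_len(n_markers) %in% skewed_markers,
                             0, 10 * marker_scales)
  }
  if (length(marker_scales) != n_markers ||
      length(marker_offsets) != n_markers)
    stop("marker scale/offset length mismatch")
  if (any(marker_scales <= 0)) stop("marker_scales must be positive")

  baseline_prevalence <- rep(baseline_prevalence, length.out = n_traits)
  if (any(baseline_prevalence <= 0 | baseline_prevalence >= 1))
    stop("baseline_prevalence must be in (0, 1)")
  if (is.null(planted_odds)) {
    kk <- seq_len(min(K, n_traits))
    planted_odds <- data.frame(subgroup = kk, trait = kk,
                               odds = rep(8, length(kk)))
  }
  if (nrow(planted_odds) > 0) {
    if (any(planted_odds$odds <= 0)) stop("planted odds ratios must be > 0")
    if (any(planted_odds$subgroup < 1 | planted_odds$subgroup > K))
      stop("planted subgroup out of range")
    if (any(planted_odds$trait < 1 | planted_odds$trait > n_traits))
      stop("planted trait out of range")
  }

  structure(list(
    n_train = n_train, n_valid = n_valid, n_markers = n_markers,
    n_subgroups = K, mixing_proportions = mixing_proportions,
    centroid_matrix = centroid_matrix, noise_sd = noise_sd,
    skewed_markers = as.integer(skewed_markers),
    marker_scales = marker_scales, marker_offsets = marker_offsets,
    age_range = age_range, age_slopes = age_slopes,
    n_traits = n_traits, baseline_prevalence = baseline_prevalence,
    planted_odds = planted_odds, missing_rate = missing_rate,
    cohort_shift = cohort_shift, seed = as.integer(seed)),
    class = "generator_spec")
}

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

.gen_one_cohort <- function(spec, n, prefix, centroids) {
  K <- spec$n_subgroups
  P <- spec$n_markers
  labels <- sample.int(K, n, replace = TRUE, prob = spec$mixing_proportions)
  ages <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  age_mid <- mean(spec$age_range)
  latent <- centroids[labels, , drop = FALSE] +
    outer(ages - age_mid, spec$age_slopes) +
    matrix(stats::rnorm(n * P, 0, spec$noise_sd), n, P)
  obs <- latent
  if (length(spec$skewed_markers))
    obs[, spec$skewed_markers] <- exp(latent[, spec$skewed_markers])
  obs <- sweep(sweep(obs, 2, spec$marker_scales, "*"),
               2, spec$marker_offsets, "+")
  if (spec$missing_rate > 0)
    obs[matrix(stats::runif(n * P) < spec$missing_rate, n, P)] <- NA
  mk <- paste0("M", sprintf("%02d", seq_len(P)))
  cohort <- cohort_matrix(paste0(prefix, seq_len(n)), ages, obs, mk)

  # traits: logit(baseline) + log(OR) for planted (subgroup, trait)
  eta <- matrix(rep(.logit(spec$baseline_prevalence), each = n), n,
                spec$n_traits)
  po <- spec$planted_odds
  for (r in seq_len(nrow(po)))
    eta[labels == po$subgroup[r], po$trait[r]] <-
      eta[labels == po$subgroup[r], po$trait[r]] + log(po$odds[r])
  tr <- matrix(as.integer(stats::runif(n * spec$n_traits) < .inv_logit(eta)),
               n, spec$n_traits)
  colnames(tr) <- paste0("TR", sprintf("%02d", seq_len(spec$n_traits)))
  list(cohort = cohort,
       traits = trait_table(cohort$sample_ids, tr),
       labels = labels)
}

#' Generate a paired training/validation cohort with known truth
#'
#' Both cohorts are i.i.d. draws from the process described by `spec`
#' (optionally with a small centroid perturbation on the validation side via
#' `cohort_shift`). The returned truth record carries the latent subgroup
#' label of every sample, the planted (subgroup, trait) pairs and the true
#' per-marker age slopes, for benchmarking recovery.
#'
#' @param spec a [generator_spec()].
#' @return A list of class `cohort_pair` with elements `train`, `train_traits`,
#'   `valid`, `valid_traits` and `truth` (list: `train_labels`,
#'   `valid_labels`, `planted`, `age_slopes`).
#' @export
generate_cohort_pair <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(spec$seed)
  tr <- .gen_one_cohort(spec, spec$n_train, "T", spec$centroid_matrix)
  cen_v <- spec$centroid_matrix
  if (spec$cohort_shift > 0)
    cen_v <- cen_v + matrix(stats::rnorm(length(cen_v), 0, spec$cohort_shift),
                            nrow(cen_v))
  va <- .gen_one_cohort(spec, spec$n_valid, "V", cen_v)
  structure(list(
    train = tr$cohort, train_traits = tr$traits,
    valid = va$cohort, valid_traits = va$traits,
    truth = list(train_labels = tr$labels, valid_labels = va$labels,
                 planted = spec$planted_odds,
                 age_slopes = spec$age_slopes * spec$marker_scales)),
    class = "cohort_pair")
}

#' Write a generated cohort pair to a directory of CSV files
#'
#' Emits `train.csv`, `train_traits.csv`, `valid.csv`, `valid_traits.csv` and
#' `truth.csv` (per-sample latent labels) plus `planted.csv`.
#'
#' @param pair a `cohort_pair` from [generate_cohort_pair()].
#' @param dir output directory (created if absent).
#' @export
write_cohort_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(pair$train, file.path(dir, "train.csv"))
  write_traits_csv(pair$train_traits, file.path(dir, "train_traits.csv"))
  write_cohort_csv(pair$valid, file.path(dir, "valid.csv"))
  write_traits_csv(pair$valid_traits, file.path(dir, "valid_traits.csv"))
  utils::write.csv(data.frame(
    sample_id = c(pair$train$sample_ids, pair$valid$sample_ids),
    cohort = rep(c("train", "valid"),
                 c(length(pair$truth$train_labels),
                   length(pair$truth$valid_labels))),
    subgroup = c(pair$truth$train_labels, pair$truth$valid_labels)),
    file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(pair$truth$planted, file.path(dir, "planted.csv"),
                   row.names = FALSE)
  invisible(dir)
}
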