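#' Adjusted Fisher-Pearson sample skewness
#'
#' The standardized third moment with the small-sample adjustment
#' `G1 = g1 * sqrt(n (n - 1)) / (n - 2)` where `g1 = m3 / m2^(3/2)`.
#' Values in \[-1, 1\] are treated by the pipeline as compatible with
#' normality; markers outside that band are candidates for the log transform.
#'
#' @param values numeric vector, length >= 3, non-constant.
#' @return The adjusted skewness (a real number).
#' @export
sample_skewness <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 values for skewness")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("degenerate marker: zero variance")
  m3 <- mean((values - m)^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Normal transform: log markers whose skewness leaves the normal band
#'
#' Each marker with |skewness| > 1 is replaced by its natural log; all other
#' markers are untouched. The set of transformed markers is returned for
#' provenance and for re-applying the identical transform to another cohort.
#'
#' @param cohort a [cohort_matrix()] with no missing cells.
#' @param markers optional character vector forcing the transformed set
#'   (used when freezing training-fitted pre-processing).
#' @return A list: `cohort` (transformed), `transformed` (marker names).
#' @export
normal_transform <- function(cohort, markers = NULL) {
  m <- cohort$markers
  if (is.null(markers)) {
    skews <- apply(m, 2, sample_skewness)
    markers <- cohort$marker_names[abs(skews) > 1]
  }
  for (j in markers) {
    if (any(m[, j] <= 0))
      stop(sprintf("marker %s selected for log transform has non-positive values", j))
    m[, j] <- log(m[, j])
  }
  list(cohort = cohort_matrix(cohort$sample_ids, cohort$ages, m,
                              cohort$marker_names),
       transformed = markers)
}

#' Z-score normalization of every marker
#'
#' Scales each marker to mean 0, sample standard deviation 1. The fitted
#' means and sds are returned so the same affine map can be re-applied (or
#' undone).
#'
#' @param cohort a [cohort_matrix()] with no missing cells.
#' @param center,scale optional per-marker means/sds to apply instead of
#'   refitting (frozen-parameter mode).
#' @return A list: `cohort`, `center`, `scale`.
#' @export
zscore_normalize <- function(cohort, center = NULL, scale = NULL) {
  m <- cohort$markers
  if (is.null(center)) center <- colMeans(m)
  if (is.null(scale)) scale <- apply(m, 2, stats::sd)
  if (any(scale == 0)) {
    bad <- cohort$marker_names[scale == 0]
    stop(sprintf("zero-variance marker(s): %s", paste(bad, collapse = ", ")))
  }
  m <- sweep(sweep(m, 2, center, "-"), 2, scale, "/")
  list(cohort = cohort_matrix(cohort$sample_ids, cohort$ages, m,
                              cohort$marker_names),
       center = center, scale = scale)
}

#' Linear-regression age adjustment of age-correlated markers
#'
#' For each marker whose Pearson correlation with age passes the gate
#' (p < 0.05 and |r| > 0.1), the marker is replaced by
#' `V' = V - (a*age + b) + m`, where `(a, b)` are the least-squares slope and
#' intercept of the marker on age and `m` is the marker's pre-adjustment mean.
#' Gated markers are exactly decorrelated from age on the fitting sample while
#' keeping their original mean; other markers pass through unchanged.
#'
#' @param cohort a [cohort_matrix()] with no missing cells.
#' @param model optional fitted model (from a previous call) to apply as-is.
#' @param p_gate,r_gate gate thresholds (defaults 0.05 and 0.1).
#' @return A list: `cohort`, `model` (data.frame per marker: `marker`,
#'   `adjusted`, `slope`, `intercept`, `recenter`, `r`, `p`).
#' @export
age_adjust <- function(cohort, model = NULL, p_gate = 0.05, r_gate = 0.1) {
  ages <- cohort$ages
  if (stats::sd(ages) == 0) stop("constant age vector: adjustment undefined")
  m <- cohort$markers
  n <- nrow(m)
  if (is.null(model)) {
    r <- as.numeric(stats::cor(ages, m))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    slope <- r * apply(m, 2, stats::sd) / stats::sd(ages)
    mu <- colMeans(m)
    intercept <- mu - slope * mean(ages)
    model <- data.frame(marker = cohort$marker_names,
                        adjusted = (p < p_gate) & (abs(r) > r_gate),
                        slope = slope, intercept = intercept,
                        recenter = mu, r = r, p = p)
  }
  for (i in which(model$adjusted)) {
    j <- model$marker[i]
    m[, j] <- m[, j] - (model$slope[i] * ages + model$intercept[i]) +
      model$recenter[i]
  }
  list(cohort = cohort_matrix(cohort$sample_ids, cohort$ages, m,
                              cohort$marker_names),
       model = model)
}

#' The four pre-processing pipeline variants
#' @export
pipeline_variants <- function() c("raw", "norm_transform", "zscore", "age_adjust_zscore")

#' Apply one pre-processing variant to a cohort
#'
#' Variants: `raw` (identity), `norm_transform` (skewness-gated log),
#' `zscore` (per-marker standardization), `age_adjust_zscore` (age adjustment
#' then Z-score). With `aggregate_transforms = TRUE` the variants chain
#' cumulatively (log, then standardize, then age-adjust for the later
#' variants), mirroring an "increasingly rigorous" reading of the pipeline;
#' the default keeps them distinct.
#'
#' Missing values are handled first: complete-case by default, per-marker
#' median imputation with `missing = "impute"`. The fitted transform record is
#' returned so the identical procedure can be frozen and applied to another
#' cohort via [apply_preprocess()]; the default protocol instead refits each
#' cohort independently.
#'
#' @param cohort a [cohort_matrix()].
#' @param variant one of [pipeline_variants()].
#' @param aggregate_transforms chain (log) -> (z-score) -> (age adjust)
#'   cumulatively instead of treating variants as distinct.
#' @param missing `"complete"` (drop samples with missing markers) or
#'   `"impute"` (per-marker median).
#' @return A list of class `preprocess_fit`: `cohort` (transformed),
#'   `variant`, `record` (fitted parameters), `dropped` (ids removed by
#'   complete-case filtering).
#' @export
preprocess <- function(cohort, variant = pipeline_variants(),
                       aggregate_transforms = FALSE,
                       missing = c("complete", "impute")) {
  variant <- match.arg(variant)
  missing <- match.arg(missing)
  dropped <- character(0)
  if (any(cohort$missing_mask)) {
    if (missing == "complete") {
      cohort <- cohort_complete_cases(cohort)
      dropped <- attr(cohort, "dropped")
    } else cohort <- cohort_impute_median(cohort)
  }
  record <- list(variant = variant, aggregate = aggregate_transforms)
  out <- cohort
  do_log <- variant == "norm_transform" ||
    (aggregate_transforms && variant %in% c("zscore", "age_adjust_zscore"))
  if (do_log) {
    nt <- normal_transform(out)
    out <- nt$cohort
    record$log_markers <- nt$transformed
  }
  if (variant == "age_adjust_zscore") {
    aa <- age_adjust(out)
    out <- aa$cohort
    record$age_model <- aa$model
  }
  if (variant %in% c("zscore", "age_adjust_zscore")) {
    zs <- zscore_normalize(out)
    out <- zs$cohort
    record$center <- zs$center
    record$scale <- zs$scale
  }
  structure(list(cohort = out, variant = variant, record = record,
                 dropped = dropped),
            class = "preprocess_fit")
}

#' Re-apply a fitted pre-processing record to a new cohort
#'
#' Frozen-parameter mode: uses the training-fitted log-marker set, age model
#' and Z-score center/scale instead of refitting on the new cohort.
#'
#' @param fit a `preprocess_fit` from [preprocess()].
#' @param cohort a [cohort_matrix()] with the same marker set.
#' @return A `preprocess_fit` for the new cohort.
#' @export
apply_preprocess <- function(fit, cohort) {
  stopifnot(inherits(fit, "preprocess_fit"))
  if (!identical(cohort$marker_names, fit$cohort$marker_names))
    stop("marker sets differ between fitted and new cohort")
  dropped <- character(0)
  if (any(cohort$missing_mask)) {
    cohort <- cohort_complete_cases(cohort)
    dropped <- attr(cohort, "dropped")
  }
  rec <- fit$record
  out <- cohort
  if (!is.null(rec$log_markers))
    out <- normal_transform(out, markers = rec$log_markers)$cohort
  if (!is.null(rec$age_model))
    out <- age_adjust(out, model = rec$age_model)$cohort
  if (!is.null(rec$center))
    out <- zscore_normalize(out, center = rec$center, scale = rec$scale)$cohort
  structure(list(cohort = out, variant = fit$variant, record = rec,
                 dropped = dropped),
            class = "preprocess_fit")
}
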