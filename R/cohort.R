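#' Construct a cohort matrix
#'
#' A cohort matrix holds one cohort's biomarker panel: a samples x markers
#' numeric matrix together with sample identifiers, ages in years and an
#' explicit missingness mask. It is the common currency of the pre-processing
#' and clustering steps.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param ages numeric vector of ages in years; the pipeline mirrors the
#'   adults-only design, so ages must be >= 20.
#' @param markers numeric matrix, samples x markers; `NA` marks missing cells.
#' @param marker_names optional character vector of marker names; defaults to
#'   the column names of `markers`.
#' @return An object of class `cohort_matrix`.
#' @export
cohort_matrix <- function(sample_ids, ages, markers, marker_names = NULL) {
  markers <- as.matrix(markers)
  storage.mode(markers) <- "double"
  if (is.null(marker_names)) marker_names <- colnames(markers)
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(ncol(markers)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (length(sample_ids) != nrow(markers))
    stop("sample_ids length does not match marker rows")
  if (length(ages) != nrow(markers))
    stop("ages length does not match marker rows")
  if (length(marker_names) != ncol(markers))
    stop("marker_names length does not match marker columns")
  if (any(is.infinite(markers))) stop("marker matrix contains infinities")
  if (any(!is.na(ages) & ages < 20))
    stop("ages below 20 are outside the supported population filter")
  dimnames(markers) <- list(sample_ids, marker_names)
  structure(
    list(sample_ids = sample_ids,
         ages = as.numeric(ages),
         markers = markers,
         marker_names = marker_names,
         missing_mask = is.na(markers)),
    class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d samples x %d markers, %d missing cells\n",
              nrow(x$markers), ncol(x$markers), sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.cohort_matrix <- function(x) dim(x$markers)

#' Subset a cohort matrix by sample index or id
#'
#' @param cohort a [cohort_matrix()].
#' @param i integer or character index of samples to keep.
#' @return A `cohort_matrix` restricted to the selected samples.
#' @export
cohort_subset <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$sample_ids)
  cohort_matrix(cohort$sample_ids[i], cohort$ages[i],
                cohort$markers[i, , drop = FALSE], cohort$marker_names)
}

#' Drop samples with any missing marker value
#'
#' Complete-case restriction: the default missing-data policy of the pipeline.
#' The ids of dropped samples are attached as attribute `"dropped"` for the
#' run log.
#'
#' @param cohort a [cohort_matrix()].
#' @return A complete-case `cohort_matrix`.
#' @export
cohort_complete_cases <- function(cohort) {
  keep <- rowSums(cohort$missing_mask) == 0
  out <- cohort_subset(cohort, which(keep))
  attr(out, "dropped") <- cohort$sample_ids[!keep]
  out
}

#' Impute missing marker values by the per-marker median
#'
#' Alternative to [cohort_complete_cases()] for cohorts where dropping samples
#' is too costly.
#'
#' @param cohort a [cohort_matrix()].
#' @return A `cohort_matrix` with no missing cells.
#' @export
cohort_impute_median <- function(cohort) {
  m <- cohort$markers
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- stats::median(m[, j], na.rm = TRUE)
  }
  cohort_matrix(cohort$sample_ids, cohort$ages, m, cohort$marker_names)
}

#' Construct a trait table
#'
#' Binary health/lifestyle labels per sample. Values are 1 (positive),
#' 0 (negative) or `NA` (unknown / item nonresponse).
#'
#' @param sample_ids character vector of sample identifiers.
#' @param traits data.frame or matrix of 0/1/NA values, one column per trait.
#' @return An object of class `trait_table`.
#' @export
trait_table <- function(sample_ids, traits) {
  traits <- as.matrix(traits)
  storage.mode(traits) <- "integer"
  if (!all(traits %in% c(0L, 1L, NA_integer_)))
    stop("trait values must be 0, 1 or NA")
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(traits))
    stop("sample_ids length does not match trait rows")
  if (is.null(colnames(traits)))
    colnames(traits) <- paste0("TR", sprintf("%02d", seq_len(ncol(traits))))
  rownames(traits) <- sample_ids
  structure(list(sample_ids = sample_ids, traits = traits),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("<trait_table> %d samples x %d traits\n",
              nrow(x$traits), ncol(x$traits)))
  invisible(x)
}

#' Write a cohort matrix to CSV
#'
#' Layout: `sample_id`, `age_years`, then one column per marker. Missing cells
#' are written as empty fields.
#'
#' @param cohort a [cohort_matrix()].
#' @param path output file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- data.frame(sample_id = cohort$sample_ids,
                   age_years = cohort$ages,
                   cohort$markers, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort matrix from CSV written by [write_cohort_csv()]
#'
#' @param path input file path.
#' @return A [cohort_matrix()].
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("sample_id", "age_years")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: missing required columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  mk <- setdiff(names(df), need)
  cohort_matrix(df$sample_id, df$age_years,
                as.matrix(df[, mk, drop = FALSE]), mk)
}

#' Write a trait table to CSV
#'
#' @param tt a [trait_table()].
#' @param path output file path.
#' @export
write_traits_csv <- function(tt, path) {
  df <- data.frame(sample_id = tt$sample_ids, tt$traits, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trait table from CSV written by [write_traits_csv()]
#'
#' @param path input file path.
#' @return A [trait_table()].
#' @export
read_traits_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop(sprintf("%s: missing sample_id", path))
  trait_table(df$sample_id,
              df[, setdiff(names(df), "sample_id"), drop = FALSE])
}
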