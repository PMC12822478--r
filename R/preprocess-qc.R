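#' @title Normalization, filtering, feature selection and ordination QC
#' @description Median normalization on the log2 scale, missingness-based
#'   feature filtering, MAD variance filtering, PCA ordination and IRS
#'   replicate reproducibility — the QC layer every analysis matrix passes
#'   through before testing.
#' @name preprocess-qc
NULL

#' Log2 + per-sample median normalization
#'
#' For raw-scale input, log2-transforms then subtracts each sample's median
#' over non-missing values; for input already on the log2 scale
#' (`input_scale = "log2"`), only the median subtraction is applied.
#' A second call on an already-normalized matrix is a no-op.
#'
#' @param m An `omics_matrix`.
#' @param input_scale `"log2"` (default; the on-disk convention) or `"raw"`
#'   for positive raw intensities.
#' @return Normalized `omics_matrix` (per-sample median 0, `is_normalized`
#'   set).
#' @export
normalize_log2_median <- function(m, input_scale = c("log2", "raw")) {
  input_scale <- match.arg(input_scale)
  if (m$is_normalized) return(m)
  v <- m$values
  if (input_scale == "raw") {
    bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("nonpositive raw intensity at feature %s, sample %s",
                   rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
    }
    v <- log2(v)
  }
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0)) {
    stop("all-missing sample column: ", colnames(v)[which(n_obs == 0)[1]])
  }
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  v <- sweep(v, 2, med, "-")
  omics_matrix(v, m$layer, is_normalized = TRUE)
}

#' Filter features by missingness
#'
#' Keeps features whose missing fraction is strictly below the threshold.
#' Never removes samples; feature order is preserved.
#'
#' @param m An `omics_matrix`.
#' @param max_missing_frac Threshold in \[0, 1\] (strict `<`).
#' @param samples Optional sample subset defining the scope (default: all).
#' @return Filtered `omics_matrix`; number of removed features is reported
#'   via [message()].
#' @export
filter_by_missingness <- function(m, max_missing_frac, samples = NULL) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  v <- if (is.null(samples)) m$values else m$values[, samples, drop = FALSE]
  frac <- rowMeans(is.na(v))
  keep <- frac < max_missing_frac | (max_missing_frac == 1)
  message(sprintf("missingness filter (< %.2f): kept %d / %d features",
                  max_missing_frac, sum(keep), length(keep)))
  omics_matrix(m$values[keep, , drop = FALSE], m$layer, m$is_normalized)
}

#' Missing fraction per feature
#' @param m An `omics_matrix`.
#' @param samples Optional sample scope.
#' @return Named numeric vector.
#' @export
missing_fraction <- function(m, samples = NULL) {
  v <- if (is.null(samples)) m$values else m$values[, samples, drop = FALSE]
  rowMeans(is.na(v))
}

#' Select the most variant features by raw MAD
#'
#' Median absolute deviation on the log2 scale, without the 1.4826
#' consistency constant, strict `>` threshold — the bare "MAD > 1"
#' convention for picking clustering features. Features with fewer than 3
#' non-missing values are excluded with a warning.
#'
#' @param m A normalized `omics_matrix`.
#' @param mad_threshold Strict lower bound on raw MAD.
#' @param samples Optional sample scope.
#' @return Character vector of selected feature ids (input order).
#' @export
mad_select <- function(m, mad_threshold, samples = NULL) {
  v <- if (is.null(samples)) m$values else m$values[, samples, drop = FALSE]
  n_obs <- rowSums(!is.na(v))
  if (any(n_obs < 3)) {
    warning(sum(n_obs < 3), " features with < 3 non-missing values excluded from MAD selection")
  }
  mads <- apply(v, 1, function(x) {
    x <- x[!is.na(x)]
    stats::median(abs(x - stats::median(x)))
  })
  rownames(v)[n_obs >= 3 & mads > mad_threshold]
}

#' PCA ordination of samples
#'
#' Centered PCA on features x samples input (samples are observations).
#' Missing values are mean-imputed per feature for the ordination only.
#' Component signs are fixed by the largest-absolute-loading-positive
#' convention so repeated runs are identical.
#'
#' @param m An `omics_matrix`.
#' @param n_components Number of components (<= min(dim)).
#' @param samples Optional sample scope.
#' @return List with `coordinates` (samples x components), `variance_explained`.
#' @export
pca_embed <- function(m, n_components = 2, samples = NULL) {
  v <- if (is.null(samples)) m$values else m$values[, samples, drop = FALSE]
  if (n_components > min(dim(v))) {
    stop("n_components exceeds matrix rank bound min(n_features, n_samples)")
  }
  # mean-impute per feature for ordination only
  imp <- t(apply(v, 1, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  }))
  imp <- imp[apply(imp, 1, function(x) all(is.finite(x))), , drop = FALSE]
  pc <- stats::prcomp(t(imp), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) coords[, j] <- -coords[, j]
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = coords, variance_explained = ve[seq_len(k)])
}

#' IRS replicate reproducibility
#'
#' Pairwise Spearman correlations between internal-reference-sample
#' columns over mutually non-missing features; the platform-stability QC.
#'
#' @param m An `omics_matrix` containing the IRS columns.
#' @param irs_sample_ids Character vector (>= 2) of IRS column ids.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
irs_reproducibility <- function(m, irs_sample_ids) {
  missing <- setdiff(irs_sample_ids, sample_ids(m))
  if (length(missing)) stop("unknown IRS sample id: ", missing[1])
  if (length(irs_sample_ids) < 2) stop("need >= 2 IRS columns")
  v <- m$values[, irs_sample_ids, drop = FALSE]
  k <- ncol(v)
  out <- diag(1, k)
  dimnames(out) <- list(irs_sample_ids, irs_sample_ids)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- spearman_corr(v[, i], v[, j])$rho
    out[i, j] <- out[j, i] <- r
  }
  out
}

#' Drop IRS columns from an analysis matrix
#' @param m An `omics_matrix`.
#' @return Matrix without `IRS_*` columns.
#' @export
drop_irs <- function(m) {
  keep <- !grepl("^IRS_", sample_ids(m))
  omics_matrix(m$values[, keep, drop = FALSE], m$layer, m$is_normalized)
}

#' Full QC report for one layer
#'
#' @param m An `omics_matrix` (pre-normalization).
#' @param input_scale Passed to [normalize_log2_median()].
#' @param n_components PCA components.
#' @return List: `normalized` matrix, `median_before`/`median_after`,
#'   `missing_frac`, `irs_cor` (NULL if no IRS columns), `pca`.
#' @export
qc_report <- function(m, input_scale = "log2", n_components = 2) {
  med_before <- apply(m$values, 2, stats::median, na.rm = TRUE)
  norm <- normalize_log2_median(m, input_scale)
  med_after <- apply(norm$values, 2, stats::median, na.rm = TRUE)
  irs_ids <- grep("^IRS_", sample_ids(norm), value = TRUE)
  irs_cor <- if (length(irs_ids) >= 2) irs_reproducibility(norm, irs_ids) else NULL
  analysis <- drop_irs(norm)
  list(
    normalized = analysis,
    median_before = med_before,
    median_after = med_after,
    missing_frac = mean(is.na(analysis$values)),
    irs_cor = irs_cor,
    pca = pca_embed(analysis, n_components)
  )
}
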