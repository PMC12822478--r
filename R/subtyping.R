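#' @title Consensus-clustering subtype discovery
#' @description Resampling-based consensus clustering (subsample samples,
#'   z-score features, k-means; consensus = co-cluster frequency among
#'   co-sampled pairs), hierarchical consensus cut for final labels, CDF /
#'   delta-area / PAC k-selection, and canonical C1/C2 labeling by a
#'   metabolism signature score.
#' @name subtyping
NULL

#' Consensus clustering over a k range
#'
#' For each of `n_iter` iterations, subsamples `resample_frac` of the
#' samples without replacement, z-scores each feature across the
#' subsample, and runs k-means (Euclidean, `nstart` restarts). The
#' consensus matrix entry (i, j) is the fraction of co-sampled iterations
#' in which i and j landed in the same cluster. Final labels per k come
#' from a hierarchical (average-linkage) cut of 1 - consensus.
#' Missing values are mean-imputed per feature for clustering only.
#' Deterministic given `seed`.
#'
#' @param matrix_ Normalized `omics_matrix`.
#' @param features Feature ids to cluster on (e.g. from [mad_select()]).
#' @param samples Optional sample scope.
#' @param k_range Candidate cluster counts (default 2:6).
#' @param resample_frac Subsampling fraction (default 0.8).
#' @param n_iter Iterations (default 250).
#' @param nstart k-means restarts (default 10).
#' @param seed Mandatory RNG seed.
#' @return A `consensus_result`: `consensus` (list of matrices per k),
#'   `labels` (list per k), `tallies` (co-cluster / co-sample counts per k,
#'   for audit), `k_range`, `params`.
#' @export
consensus_cluster <- function(matrix_, features, samples = NULL,
                              k_range = 2:6, resample_frac = 0.8,
                              n_iter = 250, nstart = 10, seed,
                              store_assignments = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  v <- matrix_$values[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  n <- ncol(v)
  if (max(k_range) > n) stop("k exceeds the number of samples")
  if (n < 2 * max(k_range)) stop("need at least 2 * max(k_range) samples")
  # mean-impute per feature (clustering only), drop all-missing features
  v <- t(apply(v, 1, function(x) { x[is.na(x)] <- mean(x, na.rm = TRUE); x }))
  v <- v[apply(v, 1, function(x) all(is.finite(x))), , drop = FALSE]
  ids <- colnames(v)

  n_sub <- max(2, round(resample_frac * n))
  set.seed(seed)
  sub_idx <- lapply(seq_len(n_iter), function(i) sort(sample.int(n, n_sub)))
  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(k_range)
  co_sample <- matrix(0, n, n)
  assignments <- if (store_assignments) vector("list", n_iter) else NULL
  for (it in seq_len(n_iter)) {
    idx <- sub_idx[[it]]
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    x <- v[, idx, drop = FALSE]
    x <- t(scale(t(x)))                       # z-score features on the subsample
    x <- x[apply(x, 1, function(r) all(is.finite(r))), , drop = FALSE]
    if (store_assignments) assignments[[it]] <- list(idx = idx, clusters = list())
    for (k in k_range) {
      cl <- stats::kmeans(t(x), centers = k, nstart = nstart, iter.max = 50)$cluster
      same <- outer(cl, cl, "==") * 1
      ck <- as.character(k)
      co_cluster[[ck]][idx, idx] <- co_cluster[[ck]][idx, idx] + same
      if (store_assignments) assignments[[it]]$clusters[[ck]] <- cl
    }
  }
  consensus <- lapply(co_cluster, function(cc) {
    m <- cc / pmax(co_sample, 1)
    m[co_sample == 0] <- NA
    diag(m) <- 1
    dimnames(m) <- list(ids, ids)
    m
  })
  labels <- lapply(seq_along(k_range), function(i) {
    m <- consensus[[i]]
    hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
    stats::setNames(stats::cutree(hc, k = k_range[i]), ids)
  })
  names(labels) <- as.character(k_range)
  structure(
    list(consensus = consensus, labels = labels,
         tallies = list(co_cluster = co_cluster, co_sample = co_sample),
         assignments = assignments,
         k_range = k_range, sample_ids = ids,
         params = list(resample_frac = resample_frac, n_iter = n_iter,
                       nstart = nstart, seed = seed,
                       n_features = nrow(v))),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d samples, k in {%s}, %d iterations\n",
              length(x$sample_ids), paste(x$k_range, collapse = ","),
              x$params$n_iter))
  invisible(x)
}

#' Mean within-cluster consensus at a given k
#' @param result A `consensus_result`.
#' @param k Cluster count.
#' @return Mean consensus over within-cluster off-diagonal pairs.
#' @export
within_cluster_consensus <- function(result, k) {
  m <- result$consensus[[as.character(k)]]
  lab <- result$labels[[as.character(k)]]
  same <- outer(lab, lab, "==")
  diag(same) <- FALSE
  mean(m[same], na.rm = TRUE)
}

#' Select the number of clusters
#'
#' Consensus-CDF based selection: the chosen k maximizes the relative
#' delta-area of the CDF (the k = min case uses the absolute area), with
#' the proportion of ambiguous clustering (PAC, consensus in (0.1, 0.9))
#' reported as a secondary criterion. Overridable via `override_k`.
#'
#' @param result A `consensus_result`.
#' @param override_k Force this k regardless of the criterion.
#' @return List: `k`, `report` (per-k area, delta_area, PAC, mean
#'   within-cluster consensus), `labels` for the chosen k.
#' @export
select_k <- function(result, override_k = NULL) {
  ks <- result$k_range
  if (length(ks) < 2 && is.null(override_k)) stop("need >= 2 candidate k")
  grid <- seq(0, 1, by = 0.01)
  area <- vapply(as.character(ks), function(ck) {
    vals <- result$consensus[[ck]][upper.tri(result$consensus[[ck]])]
    cdf <- stats::ecdf(vals)(grid)
    sum(cdf) * 0.01
  }, numeric(1))
  delta <- c(area[1], diff(area) / area[-length(area)])
  pac <- vapply(as.character(ks), function(ck) {
    vals <- result$consensus[[ck]][upper.tri(result$consensus[[ck]])]
    mean(vals > 0.1 & vals < 0.9, na.rm = TRUE)
  }, numeric(1))
  wcc <- vapply(ks, function(k) within_cluster_consensus(result, k), numeric(1))
  report <- data.frame(k = ks, area = area, delta_area = delta, pac = pac,
                       within_cluster_consensus = wcc)
  k <- if (!is.null(override_k)) override_k else ks[which.max(delta)]
  if (!as.character(k) %in% names(result$labels)) stop("k = ", k, " was not evaluated")
  list(k = k, report = report, labels = result$labels[[as.character(k)]])
}

#' Canonicalize cluster labels to C1/C2
#'
#' For k = 2: the cluster with the higher median metabolism-signature
#' score is C1 (the metabolism subtype naming convention); without a
#' metabolism set, the larger cluster is C1. For k > 2 clusters are
#' renamed C1..Ck by decreasing size.
#'
#' @param labels Named integer cluster assignment.
#' @param matrix_ Optional `omics_matrix` for the score convention.
#' @param metabolism_set Optional character vector of metabolism genes.
#' @return Named character vector of `C*` labels.
#' @export
canonical_subtype_labels <- function(labels, matrix_ = NULL, metabolism_set = NULL) {
  ks <- sort(unique(labels))
  if (length(ks) == 2 && !is.null(matrix_) && !is.null(metabolism_set)) {
    score <- sample_signature_score(matrix_, metabolism_set, min_frac = 0)
    med <- vapply(ks, function(k) {
      stats::median(score[names(labels)[labels == k]], na.rm = TRUE)
    }, numeric(1))
    ord <- ks[order(-med)]
  } else {
    ord <- ks[order(-table(labels)[as.character(ks)])]
  }
  new <- stats::setNames(paste0("C", seq_along(ord)), ord)
  stats::setNames(unname(new[as.character(labels)]), names(labels))
}

#' Adjusted Rand index between two labelings
#' @param a,b Label vectors (aligned by name when both are named).
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  mclust::adjustedRandIndex(a, b)
}
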