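#' @title Metastasis signature sets, preranked GSEA and signature scoring
#' @description Builds LM-/T-enriched protein signature sets from paired
#'   differential testing, runs preranked GSEA (weighted Kolmogorov-Smirnov
#'   running sum with gene-label permutation NES/FDR), scores samples by
#'   the median abundance of a signature, and stratifies survival by the
#'   score.
#' @name signatures-gsea
NULL

#' Build LM- and T-enriched protein signature sets
#'
#' Paired signed-rank LM vs T per protein; members must satisfy BH
#' q < `max_q`, |fold change| > `min_fc` and detection in at least
#' `min_pair_frac` of patient pairs. Direction defines membership
#' (log2fc > 0 -> LM-enriched). An optional exclusion list (e.g.
#' tissue-specific genes) removes members and sets a flag.
#'
#' @param protein Normalized protein `omics_matrix`.
#' @param clinical Clinical data frame (needs paired T and LM samples).
#' @param max_q,min_fc,min_pair_frac Construction parameters.
#' @param exclude Optional character vector of genes to remove.
#' @return List of two `signature_set`s (`lm_enriched`, `t_enriched`), each
#'   with `members`, `params`, `tissue_specific_removed`, plus the
#'   underlying `records`.
#' @export
build_enriched_sets <- function(protein, clinical, max_q = 0.05, min_fc = 1.5,
                                min_pair_frac = 0.5, exclude = NULL) {
  lm_samples <- clinical$sample_id[clinical$tissue == "LM"]
  t_samples <- clinical$sample_id[clinical$tissue == "T"]
  patients <- stats::setNames(clinical$patient_id, clinical$sample_id)
  shared <- intersect(patients[lm_samples], patients[t_samples])
  if (length(shared) < 5) stop("need at least 5 paired T/LM patients")
  diff <- differential_table(protein, lm_samples, t_samples, paired = TRUE,
                             patients = patients,
                             min_per_group = max(3, ceiling(min_pair_frac * length(shared))))
  rec <- diff$records
  pass <- rec$q < max_q & 2^abs(rec$log2fc) > min_fc &
    rec$n1 >= min_pair_frac * length(shared)
  lm_members <- rec$feature[pass & rec$log2fc > 0]
  t_members <- rec$feature[pass & rec$log2fc < 0]
  params <- list(max_q = max_q, min_fc = min_fc, min_pair_frac = min_pair_frac,
                 n_pairs = length(shared))
  make_set <- function(name, members) {
    removed <- intersect(members, exclude)
    structure(
      list(name = name, members = setdiff(members, exclude), params = params,
           tissue_specific_removed = length(removed) > 0, n_removed = length(removed)),
      class = "signature_set"
    )
  }
  list(lm_enriched = make_set("LM_enriched", lm_members),
       t_enriched = make_set("T_enriched", t_members),
       records = rec)
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %s: %d members%s\n", x$name, length(x$members),
              if (x$tissue_specific_removed) sprintf(" (%d excluded)", x$n_removed) else ""))
  invisible(x)
}

# Weighted KS running-sum enrichment score on a ranking.
# scores: named vector sorted in decreasing order; set: member ids.
gsea_es <- function(scores, set, weight = 1) {
  hit <- names(scores) %in% set
  if (!any(hit)) return(NA_real_)
  w <- abs(scores)^weight
  p_hit <- ifelse(hit, w, 0)
  denom_hit <- sum(p_hit)
  if (denom_hit == 0) p_hit[hit] <- 1 / sum(hit) else p_hit <- p_hit / denom_hit
  n_miss <- length(scores) - sum(hit)
  p_miss <- ifelse(hit, 0, 1 / n_miss)
  running <- cumsum(p_hit - p_miss)
  running[which.max(abs(running))]
}

#' Preranked GSEA
#'
#' Classical preranked gene-set enrichment: weighted KS running-sum ES on
#' the ranked list, null distribution by gene-label permutation (random
#' member sets of the same size), NES normalized separately for positive
#' and negative ES, and the GSEA-convention FDR comparing observed NES to
#' the pooled permutation NES of the same sign. Deterministic given `seed`.
#'
#' @param scores Named numeric vector of per-gene ranking metric (e.g.
#'   signed log2FC); finite values only.
#' @param sets Named list of gene sets.
#' @param n_perm Permutations per set (default 1000).
#' @param weight KS weight (1 = classic weighted; 0 = unweighted KS).
#' @param seed Mandatory RNG seed.
#' @return Data frame: `set`, `size` (in-universe), `es`, `nes`, `p`, `q`,
#'   `leading_edge` (semicolon-joined).
#' @export
preranked_gsea <- function(scores, sets, n_perm = 1000, weight = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(!is.finite(scores))) stop("ranking metric must be finite")
  scores <- sort(scores, decreasing = TRUE)
  universe <- names(scores)
  in_univ <- lapply(sets, intersect, universe)
  skip <- lengths(in_univ) == 0
  if (any(skip)) warning(sum(skip), " sets do not intersect the ranked universe; skipped")
  in_univ <- in_univ[!skip]
  if (!length(in_univ)) stop("no set intersects the ranked universe")

  obs_es <- vapply(in_univ, function(s) gsea_es(scores, s, weight), numeric(1))

  set.seed(seed)
  sizes <- lengths(in_univ)
  perm_es <- lapply(seq_along(in_univ), function(i) {
    vapply(seq_len(n_perm), function(j) {
      gsea_es(scores, sample(universe, sizes[i]), weight)
    }, numeric(1))
  })

  norm_one <- function(es, null_es) {
    pos_mean <- mean(null_es[null_es > 0])
    neg_mean <- mean(abs(null_es[null_es < 0]))
    if (es >= 0) es / pos_mean else es / neg_mean
  }
  obs_nes <- mapply(norm_one, obs_es, perm_es)
  perm_nes <- lapply(seq_along(perm_es), function(i) {
    vapply(perm_es[[i]], norm_one, numeric(1), null_es = perm_es[[i]])
  })
  pooled_nes <- unlist(perm_nes)

  p_nom <- vapply(seq_along(obs_es), function(i) {
    null_es <- perm_es[[i]]
    if (obs_es[i] >= 0) {
      same <- null_es[null_es >= 0]
      (sum(same >= obs_es[i]) + 1) / (length(same) + 1)
    } else {
      same <- null_es[null_es < 0]
      (sum(same <= obs_es[i]) + 1) / (length(same) + 1)
    }
  }, numeric(1))

  fdr <- vapply(seq_along(obs_nes), function(i) {
    nes <- obs_nes[i]
    if (nes >= 0) {
      num <- mean(pooled_nes[pooled_nes >= 0] >= nes)
      den <- mean(obs_nes[obs_nes >= 0] >= nes)
    } else {
      num <- mean(pooled_nes[pooled_nes < 0] <= nes)
      den <- mean(obs_nes[obs_nes < 0] <= nes)
    }
    if (is.na(den) || den == 0) return(1)
    min(1, num / den)
  }, numeric(1))

  leading <- vapply(seq_along(in_univ), function(i) {
    s <- in_univ[[i]]
    hit <- names(scores) %in% s
    w <- abs(scores)^weight
    p_hit <- ifelse(hit, w, 0)
    if (sum(p_hit) > 0) p_hit <- p_hit / sum(p_hit)
    n_miss <- length(scores) - sum(hit)
    running <- cumsum(p_hit - ifelse(hit, 0, 1 / n_miss))
    peak <- which.max(abs(running))
    le <- if (running[peak] >= 0) names(scores)[seq_len(peak)][hit[seq_len(peak)]]
          else names(scores)[peak:length(scores)][hit[peak:length(scores)]]
    paste(le, collapse = ";")
  }, character(1))

  data.frame(
    set = names(in_univ), size = sizes, es = obs_es, nes = obs_nes,
    p = p_nom, q = fdr, leading_edge = leading,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Median signature score per sample
#'
#' Score = median abundance of the signature members in each sample; a
#' sample needs at least `min_frac` of members quantified, else its score
#' is missing (with a warning).
#'
#' @param matrix_ An `omics_matrix`.
#' @param set A `signature_set` or character vector of members.
#' @param min_frac Minimum fraction of members quantified (default 0.5).
#' @return Named numeric vector of per-sample scores.
#' @export
sample_signature_score <- function(matrix_, set, min_frac = 0.5) {
  members <- if (inherits(set, "signature_set")) set$members else set
  if (length(members) == 0) stop("empty signature set")
  present <- intersect(members, feature_ids(matrix_))
  if (!length(present)) stop("no signature member is quantified in the matrix")
  v <- matrix_$values[present, , drop = FALSE]
  frac <- colMeans(!is.na(v))
  scores <- apply(v, 2, stats::median, na.rm = TRUE)
  low <- frac < min_frac
  if (any(low)) {
    warning(sum(low), " samples with < ", min_frac * 100,
            "% of signature members quantified; score set to NA")
    scores[low] <- NA_real_
  }
  scores
}

#' Survival stratified by signature score
#'
#' Median split of per-sample scores (ties to the low stratum), one KM
#' curve per stratum, log-rank p. Scores are joined to the clinical table
#' by sample id; with multiple samples per patient, restrict `scores` to
#' one tissue first.
#'
#' @param scores Named per-sample scores (names = sample ids).
#' @param clinical Clinical data frame.
#' @return See [median_split_survival()], plus `n_used`.
#' @export
score_stratified_survival <- function(scores, clinical) {
  idx <- match(names(scores), clinical$sample_id)
  if (all(is.na(idx))) stop("no score names match clinical sample ids")
  keep <- !is.na(idx) & !is.na(scores)
  cl <- clinical[idx[keep], ]
  res <- median_split_survival(scores[keep], cl$os_time, cl$os_event)
  res$n_used <- sum(keep)
  res
}
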