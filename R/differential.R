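#' @title Layer-aware differential testing and over-representation analysis
#' @description Wilcoxon-based differential tables between sample groups
#'   (rank-sum unpaired, signed-rank paired), the per-layer fold-change /
#'   p-value threshold policy (mrna 1.5, protein 1.2, phosphosite 1.5, all
#'   at p < 0.05), and hypergeometric pathway ORA against the quantified
#'   universe.
#' @name differential
NULL

#' Default per-layer threshold policy
#'
#' Fold-change and p-value filters per layer: mrna FC > 1.5, protein
#' FC > 1.2, phosphosite FC > 1.5, each with raw p < 0.05 (strict).
#'
#' @param mrna_fc,protein_fc,phosphosite_fc Minimum fold change per layer.
#' @param max_p Maximum raw p-value.
#' @return A `threshold_policy` list.
#' @export
threshold_policy <- function(mrna_fc = 1.5, protein_fc = 1.2,
                             phosphosite_fc = 1.5, max_p = 0.05) {
  fc <- c(mrna = mrna_fc, protein = protein_fc, phosphosite = phosphosite_fc)
  if (any(fc <= 1)) stop("fold-change thresholds must exceed 1")
  structure(list(fold_change = fc, max_p = max_p), class = "threshold_policy")
}

#' Differential table between two sample groups
#'
#' Per-feature Wilcoxon test: signed-rank on per-patient differences when
#' `paired = TRUE` (groups matched by `patients`), rank-sum otherwise.
#' log2 fold change is the difference of group means of non-missing log2
#' values (group1 minus group2). Features with fewer than `min_per_group`
#' non-missing values in either group are skipped and counted; BH across
#' tested features.
#'
#' @param layer_matrix Normalized `omics_matrix`.
#' @param group1,group2 Disjoint character vectors of sample ids.
#' @param paired Paired mode (requires `patients`).
#' @param patients Named vector sample_id -> patient_id (paired mode).
#' @param min_per_group Minimum non-missing values per group (default 3).
#' @return List: `records` data frame (`feature`, `layer`, `log2fc`, `p`,
#'   `q`, `direction`, `n1`, `n2`, `paired`), `n_skipped`.
#' @export
differential_table <- function(layer_matrix, group1, group2, paired = FALSE,
                               patients = NULL, min_per_group = 3) {
  if (length(group1) == 0 || length(group2) == 0) stop("empty sample group")
  if (length(intersect(group1, group2))) stop("groups must be disjoint")
  v <- layer_matrix$values
  missing <- setdiff(c(group1, group2), colnames(v))
  if (length(missing)) stop("unknown sample ids: ", paste(utils::head(missing, 3), collapse = ", "))
  if (paired) {
    if (is.null(patients)) stop("paired mode requires a sample -> patient map")
    p1 <- patients[group1]; p2 <- patients[group2]
    shared <- intersect(p1, p2)
    group1 <- group1[match(shared, p1)]
    group2 <- group2[match(shared, p2)]
    if (length(shared) < min_per_group) stop("too few matched patients for paired testing")
  }
  v1 <- v[, group1, drop = FALSE]
  v2 <- v[, group2, drop = FALSE]

  n_skipped <- 0L
  rows <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    x <- v1[i, ]; y <- v2[i, ]
    if (paired) {
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_per_group) { n_skipped <- n_skipped + 1L; next }
      d <- x[ok] - y[ok]
      res <- suppressWarnings(wilcoxon_signed_rank(d))
      n1 <- n2 <- sum(ok)
      lfc <- mean(d)
    } else {
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < min_per_group || length(y) < min_per_group) {
        n_skipped <- n_skipped + 1L; next
      }
      res <- suppressWarnings(wilcoxon_rank_sum(x, y))
      n1 <- length(x); n2 <- length(y)
      lfc <- mean(x) - mean(y)
    }
    rows[[i]] <- data.frame(
      feature = rownames(v)[i], log2fc = lfc, p = res$p_value,
      n1 = n1, n2 = n2, stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(records)) stop("no testable features")
  records$q <- bh_adjust(records$p)
  records$direction <- sign(records$log2fc)
  records$layer <- layer_matrix$layer
  records$paired <- paired
  records <- records[, c("feature", "layer", "log2fc", "p", "q",
                         "direction", "n1", "n2", "paired")]
  rownames(records) <- NULL
  message(sprintf("differential [%s%s]: %d features tested, %d skipped (< %d per group)",
                  layer_matrix$layer, if (paired) ", paired" else "",
                  nrow(records), n_skipped, min_per_group))
  list(records = records, n_skipped = n_skipped)
}

#' Apply the per-layer threshold policy
#'
#' Keeps records with |fold change| = 2^|log2fc| strictly above the layer's
#' fold-change threshold and raw p strictly below `max_p` (raw p, not q —
#' the printed-filter convention; q is retained for downstream use).
#'
#' @param records Differential records from one layer.
#' @param policy A [threshold_policy()].
#' @return Filtered records.
#' @export
layer_threshold_filter <- function(records, policy = threshold_policy()) {
  layer <- unique(records$layer)
  if (length(layer) != 1) stop("records must come from a single layer")
  if (!layer %in% names(policy$fold_change)) stop("unknown layer: ", layer)
  fc_min <- policy$fold_change[[layer]]
  keep <- 2^abs(records$log2fc) > fc_min & records$p < policy$max_p
  records[keep, , drop = FALSE]
}

#' Pathway over-representation analysis
#'
#' Upper-tail hypergeometric test of each gene set against the selected
#' features, with the quantified-feature universe as background; BH across
#' sets. Sets that do not intersect the universe are dropped with a
#' warning; overlap-0 sets are reported with p = 1.
#'
#' @param selected Character vector of selected features (subset of universe).
#' @param universe Character vector of quantified features.
#' @param sets Named list of gene sets (see [load_gene_sets()]).
#' @param alpha Significance level on q.
#' @return Data frame: `set`, `set_size` (in-universe), `overlap`, `p`, `q`,
#'   `significant`, `members` (semicolon-joined overlap).
#' @export
pathway_ora <- function(selected, universe, sets, alpha = 0.05) {
  offenders <- setdiff(selected, universe)
  if (length(offenders)) {
    stop("selected features outside the universe: ",
         paste(utils::head(offenders, 5), collapse = ", "))
  }
  universe <- unique(universe)
  selected <- unique(selected)
  in_universe <- lapply(sets, intersect, universe)
  empty <- lengths(in_universe) == 0
  if (any(empty)) {
    warning(sum(empty), " sets do not intersect the universe; skipped")
    in_universe <- in_universe[!empty]
  }
  if (!length(in_universe)) stop("no gene set intersects the universe")
  rows <- lapply(names(in_universe), function(nm) {
    members <- in_universe[[nm]]
    ov <- intersect(members, selected)
    p <- if (length(ov) == 0) 1 else {
      hypergeom_enrich(length(ov), length(members), length(selected), length(universe))
    }
    data.frame(set = nm, set_size = length(members), overlap = length(ov),
               p = p, members = paste(ov, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  out[order(out$p), c("set", "set_size", "overlap", "p", "q", "significant", "members")]
}
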