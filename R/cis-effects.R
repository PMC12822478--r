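#' @title Copy-number cis-effect scans across omics layers
#' @description Per-gene Spearman correlation of gene-level copy number with
#'   the gene's own mRNA, protein and phosphosite abundance within a tissue
#'   subset, BH-adjusted within layer, plus the multi-layer significance
#'   classification (which genes propagate their copy-number dosage to
#'   which layers) and cancer-associated-gene overlap counts.
#' @name cis-effects
NULL

#' Scan one layer for cis effects
#'
#' For each gene shared between the CNV matrix and the layer matrix,
#' computes Spearman correlation over complete sample pairs within
#' `tissue_samples`. Phosphosites are mapped to their parent gene; the
#' per-gene record keeps the most significant site (per-site records are
#' also returned for transparency).
#'
#' @param cnv CNV `omics_matrix` (gene-level).
#' @param layer_matrix mRNA/protein/phosphosite `omics_matrix`.
#' @param tissue_samples Sample ids defining the subset (e.g. all T samples).
#' @param min_pairs Minimum complete pairs per gene (default 10); genes
#'   below it are skipped and counted.
#' @param alpha Significance level on the BH q-value.
#' @return List: `records` (per-gene data frame with `gene`, `site_id`,
#'   `layer`, `rho`, `p`, `q`, `n_pairs`, `significant`), `site_records`
#'   (per-site, phosphosite layer only), `n_skipped`.
#' @export
cis_correlation_scan <- function(cnv, layer_matrix, tissue_samples,
                                 min_pairs = 10, alpha = 0.05) {
  shared_samples <- intersect(intersect(tissue_samples, sample_ids(cnv)),
                              sample_ids(layer_matrix))
  if (length(shared_samples) < min_pairs) {
    stop("fewer shared samples (", length(shared_samples),
         ") than min_pairs (", min_pairs, ")")
  }
  cv <- cnv$values[, shared_samples, drop = FALSE]
  lv <- layer_matrix$values[, shared_samples, drop = FALSE]
  feats <- rownames(lv)
  parent <- if (layer_matrix$layer == "phosphosite") site_to_gene(feats) else feats
  usable <- parent %in% rownames(cv)
  feats <- feats[usable]; parent <- parent[usable]

  n_skipped <- 0L
  rows <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    x <- cv[parent[i], ]
    y <- lv[feats[i], ]
    res <- spearman_corr(x, y, min_pairs = min_pairs)
    if (res$degenerate) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[i]] <- data.frame(
      gene = parent[i], site_id = feats[i], rho = res$rho, p = res$p,
      n_pairs = res$n, stringsAsFactors = FALSE
    )
  }
  site_records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(site_records) || nrow(site_records) == 0) {
    stop("no testable genes in cis scan")
  }
  if (layer_matrix$layer == "phosphosite") {
    # per-gene record = most significant site
    ord <- order(site_records$p)
    gene_records <- site_records[ord, ][!duplicated(site_records$gene[ord]), ]
  } else {
    gene_records <- site_records
  }
  gene_records$q <- bh_adjust(gene_records$p)
  gene_records$significant <- !is.na(gene_records$q) & gene_records$q < alpha
  gene_records$layer <- layer_matrix$layer
  gene_records <- gene_records[order(gene_records$gene), ]
  rownames(gene_records) <- NULL
  message(sprintf("cis scan [%s]: %d genes tested, %d significant (q < %g), %d skipped",
                  layer_matrix$layer, nrow(gene_records),
                  sum(gene_records$significant), alpha, n_skipped))
  list(records = gene_records, site_records = site_records, n_skipped = n_skipped)
}

#' Run the cis scan on all three expression layers
#'
#' @param cnv CNV matrix.
#' @param mrna,protein,phosphosite Layer matrices.
#' @param tissue_samples Sample subset.
#' @param min_pairs,alpha See [cis_correlation_scan()].
#' @return Named list of scan results per layer.
#' @export
cis_scan_all_layers <- function(cnv, mrna, protein, phosphosite,
                                tissue_samples, min_pairs = 10, alpha = 0.05) {
  list(
    mrna = cis_correlation_scan(cnv, mrna, tissue_samples, min_pairs, alpha),
    protein = cis_correlation_scan(cnv, protein, tissue_samples, min_pairs, alpha),
    phosphosite = cis_correlation_scan(cnv, phosphosite, tissue_samples, min_pairs, alpha)
  )
}

#' Classify genes by their multi-layer cis significance pattern
#'
#' Assigns each gene a category from its (mrna, protein, phosphosite)
#' significance pattern — `mrna_only`, `mrna+protein`, `all_three`, every
#' other combination, or `none` — and counts the overlap of each category
#' with a user-supplied cancer-associated-gene (CAG) list.
#'
#' @param scans Result of [cis_scan_all_layers()].
#' @param cag_list Optional character vector of cancer-associated genes.
#' @return List: `per_gene` (gene, per-layer significance, category,
#'   in_cag), `category_counts`, `cag_overlap` (significant-gene overlap
#'   with the CAG list per layer).
#' @export
classify_cis_venn <- function(scans, cag_list = NULL) {
  layers <- c("mrna", "protein", "phosphosite")
  sig <- lapply(scans[layers], function(s) {
    s$records$gene[s$records$significant]
  })
  all_genes <- sort(unique(unlist(lapply(scans[layers], function(s) s$records$gene))))
  pattern <- vapply(all_genes, function(g) {
    paste(ifelse(vapply(sig, function(x) g %in% x, logical(1)), "1", "0"),
          collapse = "")
  }, character(1))
  category <- c(
    "000" = "none", "100" = "mrna_only", "010" = "protein_only",
    "001" = "phospho_only", "110" = "mrna+protein", "101" = "mrna+phospho",
    "011" = "protein+phospho", "111" = "all_three"
  )[pattern]
  per_gene <- data.frame(
    gene = all_genes,
    sig_mrna = pattern %in% c("100", "110", "101", "111"),
    sig_protein = pattern %in% c("010", "110", "011", "111"),
    sig_phospho = pattern %in% c("001", "101", "011", "111"),
    category = unname(category),
    stringsAsFactors = FALSE
  )
  if (!is.null(cag_list)) per_gene$in_cag <- per_gene$gene %in% cag_list
  counts <- table(factor(per_gene$category, levels = unique(unname(category)[order(names(category))])))
  cag_overlap <- if (is.null(cag_list)) NULL else {
    vapply(sig, function(x) length(intersect(x, cag_list)), numeric(1))
  }
  list(per_gene = per_gene, category_counts = as.data.frame(counts),
       cag_overlap = cag_overlap)
}

#' Overall mRNA-protein correlation
#'
#' Per-gene Spearman correlation of mRNA with protein abundance over shared
#' samples — the standard transcript-to-protein concordance check.
#'
#' @param mrna,protein `omics_matrix` objects.
#' @param samples Optional sample scope.
#' @param min_pairs Minimum complete pairs.
#' @return Data frame with `gene`, `rho`, `p`, `q`, `n_pairs`.
#' @export
mrna_protein_correlation <- function(mrna, protein, samples = NULL, min_pairs = 10) {
  shared_s <- intersect(sample_ids(mrna), sample_ids(protein))
  if (!is.null(samples)) shared_s <- intersect(shared_s, samples)
  shared_g <- intersect(feature_ids(mrna), feature_ids(protein))
  mv <- mrna$values[shared_g, shared_s, drop = FALSE]
  pv <- protein$values[shared_g, shared_s, drop = FALSE]
  rows <- lapply(seq_along(shared_g), function(i) {
    res <- spearman_corr(mv[i, ], pv[i, ], min_pairs = min_pairs)
    if (res$degenerate) return(NULL)
    data.frame(gene = shared_g[i], rho = res$rho, p = res$p, n_pairs = res$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out$q <- bh_adjust(out$p)
  out
}
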