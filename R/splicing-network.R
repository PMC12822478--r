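#' @title Downstream alternative-splicing analysis
#' @description Consumes externally produced rMATS-style event tables:
#'   threshold filtering (FDR < 0.05 and |IncLevelDifference| > 0.1),
#'   per-event median-PSI survival scans, and the splicing-factor /
#'   AS-event Spearman correlation network.
#' @name splicing-network
NULL

#' Filter AS events by FDR and PSI difference
#'
#' Keeps events with `fdr < fdr_max` and `|inc_level_difference| >
#' min_abs_delta` (both strict).
#'
#' @param table An `as_event_table`.
#' @param fdr_max FDR threshold (default 0.05).
#' @param min_abs_delta Minimum |IncLevelDifference| (default 0.1).
#' @return Filtered `as_event_table`.
#' @export
filter_as_events <- function(table, fdr_max = 0.05, min_abs_delta = 0.1) {
  ev <- table$events
  keep <- ev$fdr < fdr_max & abs(ev$inc_level_difference) > min_abs_delta
  keep[is.na(keep)] <- FALSE
  structure(
    list(events = ev[keep, , drop = FALSE],
         psi = table$psi[keep, , drop = FALSE]),
    class = "as_event_table"
  )
}

#' Per-event survival association
#'
#' Median-PSI split per event (within the supplied samples), KM + log-rank,
#' direction = sign of the median-OS difference (+1: high PSI, poor
#' prognosis). Events with PSI present in fewer than `min_frac` of samples
#' or with constant PSI are skipped and counted.
#'
#' @param table An `as_event_table` (typically pre-filtered).
#' @param clinical Clinical table.
#' @param samples Sample scope (default: all PSI columns).
#' @param min_frac Minimum fraction of samples with PSI (default 0.8).
#' @param alpha Log-rank significance threshold for the summary counts.
#' @return List: `records` (`event_id`, `logrank_p`, `direction`,
#'   `prognosis`, `n_used`), `summary` (counts good/poor/ns), `n_skipped`.
#' @export
as_survival_scan <- function(table, clinical, samples = NULL,
                             min_frac = 0.8, alpha = 0.05) {
  psi <- table$psi
  if (!is.null(samples)) psi <- psi[, intersect(samples, colnames(psi)), drop = FALSE]
  cl <- clinical[match(colnames(psi), clinical$sample_id), ]
  ok_samples <- !is.na(cl$sample_id)
  psi <- psi[, ok_samples, drop = FALSE]
  cl <- cl[ok_samples, ]
  n_skipped <- 0L
  rows <- lapply(seq_len(nrow(psi)), function(i) {
    x <- psi[i, ]
    if (mean(!is.na(x)) < min_frac || length(unique(x[!is.na(x)])) < 2) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    sr <- tryCatch(median_split_survival(x, cl$os_time, cl$os_event),
                   error = function(e) NULL)
    if (is.null(sr)) { n_skipped <<- n_skipped + 1L; return(NULL) }
    data.frame(
      event_id = rownames(psi)[i], logrank_p = sr$test$p_value,
      direction = sr$direction,
      prognosis = if (sr$test$p_value >= alpha || sr$direction == 0) "ns"
                  else if (sr$direction > 0) "poor" else "good",
      n_used = sr$n_used %||% sum(!is.na(x)),
      stringsAsFactors = FALSE
    )
  })
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(records)) records <- data.frame(
    event_id = character(), logrank_p = numeric(), direction = integer(),
    prognosis = character(), n_used = integer()
  )
  summary <- as.data.frame(base::table(factor(records$prognosis,
                                              levels = c("good", "poor", "ns"))))
  names(summary) <- c("prognosis", "n")
  if (n_skipped) message(sprintf("AS survival scan: %d events skipped", n_skipped))
  list(records = records, summary = summary, n_skipped = n_skipped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Splicing-factor / AS-event correlation network
#'
#' Spearman correlation of every splicing-factor protein with every event's
#' PSI over shared samples; BH across the full factor x event grid; edges
#' with q < alpha retained with their sign. Pairs with fewer than 4
#' complete observations are skipped.
#'
#' @param protein Normalized protein `omics_matrix`.
#' @param factors Character vector of splicing-factor feature ids.
#' @param table An `as_event_table`.
#' @param alpha Edge significance threshold on q (default 0.05).
#' @return List: `edges` (significant: `factor`, `event_id`, `rho`, `p`,
#'   `q`, `sign`), `all_pairs` (every tested pair), `n_skipped`.
#' @export
factor_event_network <- function(protein, factors, table, alpha = 0.05) {
  missing <- setdiff(factors, feature_ids(protein))
  if (length(missing)) stop("unknown factor feature ids: ", paste(utils::head(missing, 3), collapse = ", "))
  shared <- intersect(sample_ids(protein), colnames(table$psi))
  if (length(shared) < 4) stop("fewer than 4 shared samples between protein matrix and PSI table")
  pv <- protein$values[factors, shared, drop = FALSE]
  psi <- table$psi[, shared, drop = FALSE]
  n_skipped <- 0L
  rows <- list()
  for (f in factors) for (i in seq_len(nrow(psi))) {
    res <- spearman_corr(pv[f, ], psi[i, ])
    if (res$degenerate) { n_skipped <- n_skipped + 1L; next }
    rows[[length(rows) + 1]] <- data.frame(
      factor = f, event_id = rownames(psi)[i], rho = res$rho, p = res$p,
      n = res$n, stringsAsFactors = FALSE
    )
  }
  all_pairs <- do.call(rbind, rows)
  if (is.null(all_pairs)) stop("no testable factor-event pairs")
  all_pairs$q <- bh_adjust(all_pairs$p)
  all_pairs$sign <- sign(all_pairs$rho)
  edges <- all_pairs[all_pairs$q < alpha, , drop = FALSE]
  edges <- edges[order(edges$q), ]
  rownames(edges) <- NULL
  list(edges = edges, all_pairs = all_pairs, n_skipped = n_skipped)
}
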