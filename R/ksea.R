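#' @title Kinase-substrate enrichment analysis (KSEA)
#' @description Infers differential kinase activity from the aggregate
#'   fold change of each kinase's annotated substrate phosphosites against
#'   the full quantified-site background: z = (mean_substrates -
#'   mean_background) * sqrt(m) / sd_background, two-sided normal p, BH
#'   across kinases.
#' @name ksea
NULL

#' KSEA z-scores
#'
#' @param site_log2fc Named numeric vector of per-phosphosite contrast
#'   values (e.g. paired median LM - T log2 differences); at least 20
#'   finite sites are required as background.
#' @param map Kinase-substrate map (named list kinase -> site ids).
#' @param min_substrates Kinases with fewer quantified substrates are
#'   excluded and counted (default 3).
#' @return List: `activities` data frame (`kinase`, `z`, `p`, `q`, `m`,
#'   `mean_log2fc`, `direction`), `n_excluded`.
#' @export
ksea_scores <- function(site_log2fc, map, min_substrates = 3) {
  site_log2fc <- site_log2fc[is.finite(site_log2fc)]
  if (length(site_log2fc) < 20) stop("need >= 20 quantified sites as background")
  bg_mean <- mean(site_log2fc)
  bg_sd <- stats::sd(site_log2fc)
  if (bg_sd == 0) stop("background standard deviation is zero")
  rows <- lapply(names(map), function(k) {
    subs <- intersect(map[[k]], names(site_log2fc))
    m <- length(subs)
    if (m < min_substrates) return(NULL)
    mu <- mean(site_log2fc[subs])
    z <- (mu - bg_mean) * sqrt(m) / bg_sd
    data.frame(kinase = k, z = z, p = 2 * stats::pnorm(-abs(z)), m = m,
               mean_log2fc = mu, stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  n_excluded <- sum(!keep)
  if (n_excluded) {
    message(sprintf("KSEA: %d kinases with < %d quantified substrates excluded",
                    n_excluded, min_substrates))
  }
  act <- do.call(rbind, rows[keep])
  if (is.null(act)) stop("no kinase with enough quantified substrates")
  act$q <- bh_adjust(act$p)
  act$direction <- sign(act$z)
  act <- act[order(-abs(act$z)), c("kinase", "z", "p", "q", "m", "mean_log2fc", "direction")]
  rownames(act) <- NULL
  list(activities = act, n_excluded = n_excluded,
       background = c(mean = bg_mean, sd = bg_sd, n = length(site_log2fc)))
}

#' Per-site contrast values for KSEA
#'
#' Paired mode: per-site median of per-patient (group1 - group2)
#' differences — the within-patient LM-vs-T contrast. Unpaired mode:
#' difference of group means — the C1-vs-C2 contrast.
#'
#' @param phospho Normalized phosphosite `omics_matrix`.
#' @param group1,group2 Sample id vectors.
#' @param paired Pairing flag; paired mode needs `patients`.
#' @param patients Named vector sample_id -> patient_id.
#' @param min_obs Minimum paired observations / per-group values (default 3).
#' @return Named numeric vector of per-site contrasts (untestable sites
#'   dropped).
#' @export
site_contrast <- function(phospho, group1, group2, paired = TRUE,
                          patients = NULL, min_obs = 3) {
  v <- phospho$values
  if (paired) {
    if (is.null(patients)) stop("paired contrast requires a sample -> patient map")
    p1 <- patients[group1]; p2 <- patients[group2]
    shared <- intersect(p1, p2)
    g1 <- group1[match(shared, p1)]; g2 <- group2[match(shared, p2)]
    d <- v[, g1, drop = FALSE] - v[, g2, drop = FALSE]
    n_ok <- rowSums(!is.na(d))
    out <- apply(d, 1, stats::median, na.rm = TRUE)
    out[n_ok < min_obs] <- NA_real_
  } else {
    m1 <- rowMeans(v[, group1, drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(v[, group2, drop = FALSE], na.rm = TRUE)
    n1 <- rowSums(!is.na(v[, group1, drop = FALSE]))
    n2 <- rowSums(!is.na(v[, group2, drop = FALSE]))
    out <- m1 - m2
    out[n1 < min_obs | n2 < min_obs] <- NA_real_
  }
  out[is.finite(out)]
}

#' Kinase-substrate evidence table
#'
#' For each reported kinase, lists its quantified substrates with their
#' site-level differential statistics; substrates absent from the
#' differential records are flagged with missing effect values.
#'
#' @param activities `activities` data frame from [ksea_scores()].
#' @param map Kinase-substrate map.
#' @param site_records Phosphosite differential records
#'   (see [differential_table()]).
#' @param alpha Report kinases with p below this (default 0.05; use 1 for all).
#' @return Data frame: `kinase`, `z`, `substrate`, `log2fc`, `p`, `q`,
#'   `in_diff_records`.
#' @export
substrate_annotation <- function(activities, map, site_records, alpha = 0.05) {
  sig <- activities[activities$p < alpha, , drop = FALSE]
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    k <- sig$kinase[i]
    subs <- map[[k]]
    idx <- match(subs, site_records$feature)
    data.frame(
      kinase = k, z = sig$z[i], substrate = subs,
      log2fc = site_records$log2fc[idx],
      p = site_records$p[idx], q = site_records$q[idx],
      in_diff_records = !is.na(idx),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(
    kinase = character(), z = numeric(), substrate = character(),
    log2fc = numeric(), p = numeric(), q = numeric(), in_diff_records = logical()
  )
  rownames(out) <- NULL
  out
}
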