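#' @title Cascaded biomarker nomination workflows
#' @description Two staged filters nominating subtype-specific candidates:
#'   proteins (missingness < 10% -> higher in C1-LM than all five other
#'   sample sets at FC > 1.2 & p < 0.05 -> pathway annotation -> median-split
#'   log-rank p < 0.05 in LM samples) and phosphosites (missingness -> C1 vs
#'   C2 |FC| > 1.5 & p < 0.05 -> functional score > 0.5 -> log-rank), plus
#'   the dependency-list intersection. Every candidate's full stage-by-stage
#'   audit trail is retained.
#' @name biomarker-cascade
NULL

#' Cascade threshold policy
#' @param max_missing Missingness gate (strict `<`, default 0.10).
#' @param protein_fc,phospho_fc Fold-change gates (strict `>`).
#' @param max_p Differential p gate (strict `<`).
#' @param min_functional_score Functional-score gate (strict `>`).
#' @param max_logrank_p Survival gate (strict `<`).
#' @param paired_t Use a paired test for the C1-LM vs C1-T comparison
#'   (default FALSE: unpaired rank-sum everywhere).
#' @return A `cascade_policy` list.
#' @export
cascade_policy <- function(max_missing = 0.10, protein_fc = 1.2,
                           phospho_fc = 1.5, max_p = 0.05,
                           min_functional_score = 0.5,
                           max_logrank_p = 0.05, paired_t = FALSE) {
  structure(as.list(environment()), class = "cascade_policy")
}

#' Attach per-patient subtype labels to a clinical table
#'
#' Every sample inherits its patient's LM subtype (so N and T samples can be
#' grouped by subtype in the six-set cascade construction).
#'
#' @param clinical Clinical data frame.
#' @param subtype_by_patient Named vector patient_id -> "C1"/"C2".
#' @return The clinical table with a `subtype` column.
#' @export
attach_subtypes <- function(clinical, subtype_by_patient) {
  clinical$subtype <- unname(subtype_by_patient[clinical$patient_id])
  if (any(is.na(clinical$subtype))) stop("subtype labels missing for some patients")
  clinical
}

#' Protein biomarker cascade
#'
#' Stage 1: missingness < 10% across all samples. Stage 2: the candidate
#' must be higher in C1-LM than each of the five other sample sets (C2-LM,
#' C1-T, C2-T, C1-N, C2-N) with FC > 1.2 and rank-sum p < 0.05 in every
#' comparison. Stage 3: pathway ORA annotation of survivors (reported, not
#' a filter). Stage 4: median-split log-rank p < 0.05 within LM samples.
#'
#' @param protein Normalized protein `omics_matrix`.
#' @param clinical Clinical table with per-patient subtype labels attached
#'   (see [attach_subtypes()]; N samples inherit the patient's subtype).
#' @param sets Optional gene sets for the stage-3 ORA annotation.
#' @param policy A [cascade_policy()].
#' @return List: `records` (per-candidate audit trail with stage
#'   statistics, `failed_stage`, `final_pass`), `passing` (ids), `ora`
#'   (stage-3 annotation or NULL).
#' @export
protein_biomarker_scan <- function(protein, clinical, sets = NULL,
                                   policy = cascade_policy()) {
  if (!"subtype" %in% names(clinical) || any(is.na(clinical$subtype))) {
    stop("clinical table needs subtype labels on every sample (see attach_subtypes)")
  }
  v <- drop_irs(protein)$values
  cl <- clinical[clinical$sample_id %in% colnames(v), ]
  groups <- split(cl$sample_id, paste(cl$subtype, cl$tissue, sep = "-"))
  needed <- c("C1-LM", "C2-LM", "C1-T", "C2-T", "C1-N", "C2-N")
  missing_groups <- setdiff(needed, names(groups))
  if (length(missing_groups)) stop("missing sample sets: ", paste(missing_groups, collapse = ", "))
  ref <- groups[["C1-LM"]]
  others <- needed[-1]

  miss_frac <- rowMeans(is.na(v))
  lm_cl <- cl[cl$tissue == "LM", ]

  rows <- lapply(rownames(v), function(f) {
    rec <- list(feature = f, missing_frac = miss_frac[[f]])
    if (!(rec$missing_frac < policy$max_missing)) {
      rec$failed_stage <- "missingness"
      return(rec)
    }
    x <- v[f, ref]; x <- x[!is.na(x)]
    stage2_fail <- NA_character_
    for (g in others) {
      y <- v[f, groups[[g]]]; y <- y[!is.na(y)]
      if (length(x) < 3 || length(y) < 3) { stage2_fail <- paste0(g, ":too_few"); break }
      lfc <- mean(x) - mean(y)
      p <- suppressWarnings(wilcoxon_rank_sum(x, y))$p_value
      rec[[paste0("log2fc_vs_", g)]] <- lfc
      rec[[paste0("p_vs_", g)]] <- p
      if (!(lfc > 0 && 2^lfc > policy$protein_fc && p < policy$max_p)) {
        stage2_fail <- g
        break
      }
    }
    if (!is.na(stage2_fail)) {
      rec$failed_stage <- paste0("differential:", stage2_fail)
      return(rec)
    }
    scores <- v[f, lm_cl$sample_id]
    sr <- tryCatch(
      median_split_survival(scores, lm_cl$os_time, lm_cl$os_event),
      error = function(e) NULL
    )
    if (is.null(sr)) {
      rec$failed_stage <- "survival:degenerate"
      return(rec)
    }
    rec$logrank_p <- sr$test$p_value
    if (!(rec$logrank_p < policy$max_logrank_p)) {
      rec$failed_stage <- "survival"
      return(rec)
    }
    rec$failed_stage <- NA_character_
    rec
  })
  # column union across heterogeneous rows
  all_cols <- unique(unlist(lapply(rows, names)))
  records <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    as.data.frame(r[all_cols], stringsAsFactors = FALSE)
  }))
  records$final_pass <- is.na(records$failed_stage)
  passing <- records$feature[records$final_pass]
  ora <- NULL
  stage2_pass <- records$feature[records$final_pass |
                                   startsWith(ifelse(is.na(records$failed_stage), "", records$failed_stage), "survival")]
  if (!is.null(sets) && length(stage2_pass)) {
    ora <- tryCatch(pathway_ora(stage2_pass, rownames(v), sets),
                    error = function(e) NULL)
  }
  message(sprintf("protein cascade: %d candidates, %d pass stage 1, %d pass stage 2, %d final",
                  nrow(records), sum(records$missing_frac < policy$max_missing),
                  length(stage2_pass), length(passing)))
  list(records = records, passing = passing, ora = ora)
}

#' Phosphosite biomarker cascade
#'
#' Stages: missingness < 10%; C1 vs C2 within LM samples at |FC| > 1.5 and
#' rank-sum p < 0.05; functional score > 0.5 (sites without a score are
#' recorded and excluded at this stage); median-split log-rank p < 0.05
#' within LM samples.
#'
#' @param phospho Normalized phosphosite `omics_matrix`.
#' @param annotation Site annotation data frame (see
#'   [load_site_annotation()]).
#' @param clinical Clinical table with subtype labels.
#' @param policy A [cascade_policy()].
#' @return List: `records` (audit trail), `passing`.
#' @export
phospho_biomarker_scan <- function(phospho, annotation, clinical,
                                   policy = cascade_policy()) {
  if (!"subtype" %in% names(clinical) || any(is.na(clinical$subtype))) {
    stop("clinical table needs subtype labels on every sample")
  }
  v <- drop_irs(phospho)$values
  cl <- clinical[clinical$sample_id %in% colnames(v), ]
  lm_cl <- cl[cl$tissue == "LM", ]
  c1 <- lm_cl$sample_id[lm_cl$subtype == "C1"]
  c2 <- lm_cl$sample_id[lm_cl$subtype == "C2"]
  if (length(c1) < 3 || length(c2) < 3) stop("need >= 3 LM samples per subtype")
  scores_map <- stats::setNames(annotation$functional_score, annotation$site_id)
  miss_frac <- rowMeans(is.na(v))

  rows <- lapply(rownames(v), function(f) {
    rec <- list(feature = f, missing_frac = miss_frac[[f]])
    if (!(rec$missing_frac < policy$max_missing)) {
      rec$failed_stage <- "missingness"
      return(rec)
    }
    x <- v[f, c1]; x <- x[!is.na(x)]
    y <- v[f, c2]; y <- y[!is.na(y)]
    if (length(x) < 3 || length(y) < 3) {
      rec$failed_stage <- "differential:too_few"
      return(rec)
    }
    rec$log2fc <- mean(x) - mean(y)
    rec$p <- suppressWarnings(wilcoxon_rank_sum(x, y))$p_value
    if (!(2^abs(rec$log2fc) > policy$phospho_fc && rec$p < policy$max_p)) {
      rec$failed_stage <- "differential"
      return(rec)
    }
    rec$functional_score <- if (f %in% names(scores_map)) scores_map[[f]] else NA_real_
    if (is.na(rec$functional_score) || !(rec$functional_score > policy$min_functional_score)) {
      rec$failed_stage <- "functional_score"
      return(rec)
    }
    sr <- tryCatch(
      median_split_survival(v[f, lm_cl$sample_id], lm_cl$os_time, lm_cl$os_event),
      error = function(e) NULL
    )
    if (is.null(sr)) {
      rec$failed_stage <- "survival:degenerate"
      return(rec)
    }
    rec$logrank_p <- sr$test$p_value
    if (!(rec$logrank_p < policy$max_logrank_p)) {
      rec$failed_stage <- "survival"
      return(rec)
    }
    rec$failed_stage <- NA_character_
    rec
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  records <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    as.data.frame(r[all_cols], stringsAsFactors = FALSE)
  }))
  records$final_pass <- is.na(records$failed_stage)
  message(sprintf("phospho cascade: %d candidates, %d final",
                  nrow(records), sum(records$final_pass)))
  list(records = records, passing = records$feature[records$final_pass])
}

#' Intersect C1-upregulated proteins with dependency gene lists
#'
#' Deduplicated intersection of the C1-up candidates with named dependency
#' lists (e.g. CRC- and liver-cancer-dependent genes), ranked by the
#' significance of the paired C1-LM vs paired-T contrast.
#'
#' @param c1_up_proteins Character vector of C1-upregulated proteins.
#' @param dependency_lists Named list of character vectors.
#' @param protein Normalized protein `omics_matrix`.
#' @param clinical Clinical table with subtype labels.
#' @return Data frame: `gene`, `sources`, `log2fc`, `p`, `q`, ranked by p.
#' @export
dependency_intersect <- function(c1_up_proteins, dependency_lists,
                                 protein, clinical) {
  if (!length(dependency_lists) || any(lengths(dependency_lists) == 0)) {
    stop("dependency lists must be non-empty")
  }
  membership <- lapply(dependency_lists, intersect, c1_up_proteins)
  genes <- unique(unlist(membership))
  if (!length(genes)) {
    return(data.frame(gene = character(), sources = character(),
                      log2fc = numeric(), p = numeric(), q = numeric()))
  }
  sources <- vapply(genes, function(g) {
    paste(names(dependency_lists)[vapply(membership, function(m) g %in% m, logical(1))],
          collapse = ";")
  }, character(1))
  c1_patients <- unique(clinical$patient_id[clinical$subtype == "C1"])
  cl <- clinical[clinical$patient_id %in% c1_patients, ]
  lm <- cl$sample_id[cl$tissue == "LM"]
  tt <- cl$sample_id[cl$tissue == "T"]
  patients <- stats::setNames(cl$patient_id, cl$sample_id)
  sub <- subset_omics(drop_irs(protein),
                      features = intersect(genes, feature_ids(protein)))
  diff <- differential_table(sub, lm, tt, paired = TRUE, patients = patients)
  idx <- match(genes, diff$records$feature)
  out <- data.frame(
    gene = genes, sources = sources,
    log2fc = diff$records$log2fc[idx],
    p = diff$records$p[idx], q = diff$records$q[idx],
    stringsAsFactors = FALSE
  )
  out[order(out$p), ]
}
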