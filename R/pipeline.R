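#' @title End-to-end pipeline driver
#' @description Runs every stage in dependency order on a synthetic cohort
#'   (simulate -> qc -> cis -> diff -> signatures/gsea -> ksea -> subtype ->
#'   splicing -> biomarker -> survival), writing flat TSV artifacts, a
#'   deterministic run log and a resolved-config copy. Repeat runs with the
#'   same config and seed produce byte-identical artifacts.
#' @name pipeline
NULL

PIPELINE_STAGES <- c("simulate", "qc", "cis", "diff", "signatures", "ksea",
                     "subtype", "splicing", "biomarker", "survival")

#' Pipeline configuration
#'
#' @param outdir Output directory for artifacts.
#' @param seed Global seed (feeds the cohort generator and every
#'   stochastic stage).
#' @param cohort Named list of [synthetic_config()] overrides.
#' @param stages Stages to run (dependency order is enforced; default all).
#' @param diff_policy A [threshold_policy()].
#' @param biomarker_policy A [cascade_policy()].
#' @param mad_threshold MAD feature-selection threshold for subtyping.
#' @param consensus_iter Consensus-clustering iterations.
#' @param gsea_perm GSEA permutations.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed, cohort = list(),
                            stages = PIPELINE_STAGES,
                            diff_policy = threshold_policy(),
                            biomarker_policy = cascade_policy(),
                            mad_threshold = 1,
                            consensus_iter = 250,
                            gsea_perm = 1000) {
  if (missing(outdir) || missing(seed)) stop("outdir and seed are required")
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the pipeline
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of each stage; TSV
#'   artifacts, `run.log`, `MANIFEST` and `resolved_config.json` are
#'   written under `config$outdir`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$outdir, "run.log")
  loglines <- character(0)
  log <- function(...) {
    line <- sprintf(...)
    loglines <<- c(loglines, line)
    message(line)
  }
  completed <- character(0)
  out <- list()
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% cfg$stages]

  finish <- function() {
    writeLines(loglines, logfile)
    writeLines(completed, file.path(cfg$outdir, "MANIFEST"))
    resolved <- cfg
    resolved$diff_policy <- unclass(resolved$diff_policy)
    resolved$biomarker_policy <- unclass(resolved$biomarker_policy)
    jsonlite::write_json(lapply(unclass(resolved), function(x) x),
                         file.path(cfg$outdir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  on.exit(finish())

  ## simulate -------------------------------------------------------------
  cohort_args <- utils::modifyList(list(seed = cfg$seed), cfg$cohort)
  sc <- do.call(synthetic_config, cohort_args)
  bundle <- generate_cohort(sc)
  if ("simulate" %in% stages) {
    write_cohort(bundle, file.path(cfg$outdir, "cohort"))
    write_tsv(cohort_summary(bundle), file.path(cfg$outdir, "cohort_summary.tsv"))
    log("stage simulate: %d patients, %d genes, seed %d",
        sc$n_patients, sc$n_genes, cfg$seed)
    completed <- c(completed, "simulate")
  }
  cl <- bundle$clinical
  patients <- stats::setNames(cl$patient_id, cl$sample_id)
  lm_samples <- cl$sample_id[cl$tissue == "LM"]
  t_samples <- cl$sample_id[cl$tissue == "T"]

  ## qc -------------------------------------------------------------------
  norm <- list(
    cnv = bundle$cnv,
    mrna = suppressMessages(normalize_log2_median(bundle$mrna)),
    protein = suppressMessages(normalize_log2_median(bundle$protein)),
    phosphosite = suppressMessages(normalize_log2_median(bundle$phosphosite))
  )
  analysis <- lapply(norm, drop_irs)
  if ("qc" %in% stages) {
    irs_ids <- grep("^IRS_", sample_ids(norm$protein), value = TRUE)
    irs_cor <- if (length(irs_ids) >= 2) irs_reproducibility(norm$protein, irs_ids) else NULL
    pca <- pca_embed(analysis$protein, 2)
    write_tsv(data.frame(sample_id = rownames(pca$coordinates),
                         pc1 = pca$coordinates[, 1], pc2 = pca$coordinates[, 2]),
              file.path(cfg$outdir, "pca_coordinates.tsv"))
    qc <- data.frame(
      metric = c(paste0("missing_frac_", names(analysis)),
                 "irs_min_rho", "pc1_var", "pc2_var"),
      value = c(vapply(analysis, function(m) mean(is.na(m$values)), numeric(1)),
                if (is.null(irs_cor)) NA else min(irs_cor[upper.tri(irs_cor)]),
                pca$variance_explained[1], pca$variance_explained[2])
    )
    write_tsv(qc, file.path(cfg$outdir, "qc_report.tsv"))
    out$qc <- list(irs_cor = irs_cor, pca = pca)
    log("stage qc: normalization applied; IRS min rho = %.3f",
        if (is.null(irs_cor)) NA else min(irs_cor[upper.tri(irs_cor)]))
    completed <- c(completed, "qc")
  }

  ## cis ------------------------------------------------------------------
  if ("cis" %in% stages) {
    scans <- suppressMessages(cis_scan_all_layers(
      analysis$cnv, analysis$mrna, analysis$protein, analysis$phosphosite,
      tissue_samples = t_samples
    ))
    venn <- classify_cis_venn(scans)
    all_rec <- do.call(rbind, lapply(scans, function(s) s$records))
    write_tsv(all_rec, file.path(cfg$outdir, "cis_records.tsv"))
    write_tsv(venn$per_gene, file.path(cfg$outdir, "cis_venn.tsv"))
    out$cis <- list(scans = scans, venn = venn)
    counts <- vapply(scans, function(s) sum(s$records$significant), numeric(1))
    log("stage cis (q < 0.05): significant genes mrna=%d protein=%d phosphosite=%d",
        counts[1], counts[2], counts[3])
    completed <- c(completed, "cis")
  }

  ## diff -----------------------------------------------------------------
  if ("diff" %in% stages) {
    diffs <- lapply(c("mrna", "protein", "phosphosite"), function(layer) {
      d <- suppressMessages(differential_table(
        analysis[[layer]], lm_samples, t_samples,
        paired = TRUE, patients = patients
      ))
      d$records
    })
    names(diffs) <- c("mrna", "protein", "phosphosite")
    all_diff <- do.call(rbind, diffs)
    write_tsv(all_diff, file.path(cfg$outdir, "diff_records.tsv"))
    filt <- lapply(diffs, layer_threshold_filter, policy = cfg$diff_policy)
    write_tsv(do.call(rbind, filt), file.path(cfg$outdir, "diff_filtered.tsv"))
    out$diff <- diffs
    log("stage diff LM vs T (fc > %s/%s/%s, p < %g): %d/%d/%d features pass",
        cfg$diff_policy$fold_change[["mrna"]], cfg$diff_policy$fold_change[["protein"]],
        cfg$diff_policy$fold_change[["phosphosite"]], cfg$diff_policy$max_p,
        nrow(filt$mrna), nrow(filt$protein), nrow(filt$phosphosite))
    completed <- c(completed, "diff")
  }

  ## signatures -----------------------------------------------------------
  if ("signatures" %in% stages) {
    sigs <- suppressMessages(build_enriched_sets(analysis$protein, cl))
    sets <- list(LM_enriched = sigs$lm_enriched$members,
                 T_enriched = sigs$t_enriched$members)
    sets <- sets[lengths(sets) > 0]
    write_gene_sets(sets, file.path(cfg$outdir, "signature_sets.gmt"))
    gsea <- NULL
    if (length(sets)) {
      ranking <- stats::setNames(sigs$records$log2fc, sigs$records$feature)
      gsea <- preranked_gsea(ranking, sets, n_perm = cfg$gsea_perm, weight = 1,
                             seed = cfg$seed + 1)
      write_tsv(gsea, file.path(cfg$outdir, "gsea_results.tsv"))
    }
    surv <- NULL
    if (length(sigs$lm_enriched$members)) {
      score <- suppressWarnings(
        sample_signature_score(analysis$protein, sigs$lm_enriched)
      )
      surv <- score_stratified_survival(score[t_samples], cl)
      out$signatures <- list(sets = sigs, gsea = gsea, score = score,
                             survival = surv)
    } else {
      out$signatures <- list(sets = sigs, gsea = gsea)
    }
    log("stage signatures: LM set n=%d, T set n=%d; LM-set NES=%s q=%s; score logrank p=%s",
        length(sigs$lm_enriched$members), length(sigs$t_enriched$members),
        if (!is.null(gsea) && "LM_enriched" %in% gsea$set)
          sprintf("%.2f", gsea$nes[gsea$set == "LM_enriched"]) else "NA",
        if (!is.null(gsea) && "LM_enriched" %in% gsea$set)
          sprintf("%.3g", gsea$q[gsea$set == "LM_enriched"]) else "NA",
        if (!is.null(surv)) sprintf("%.3g", surv$test$p_value) else "NA")
    completed <- c(completed, "signatures")
  }

  ## ksea -----------------------------------------------------------------
  if ("ksea" %in% stages) {
    contrast <- site_contrast(analysis$phosphosite, lm_samples, t_samples,
                              paired = TRUE, patients = patients)
    kres <- suppressMessages(ksea_scores(contrast, bundle$kinase_map))
    write_tsv(kres$activities, file.path(cfg$outdir, "kinase_activities.tsv"))
    if ("diff" %in% names(out)) {
      evid <- substrate_annotation(kres$activities, bundle$kinase_map,
                                   out$diff$phosphosite)
      write_tsv(evid, file.path(cfg$outdir, "kinase_substrate_evidence.tsv"))
    }
    out$ksea <- kres
    log("stage ksea: %d kinases scored, %d significant (q < 0.05)",
        nrow(kres$activities), sum(kres$activities$q < 0.05))
    completed <- c(completed, "ksea")
  }

  ## subtype --------------------------------------------------------------
  if ("subtype" %in% stages) {
    feats <- mad_select(analysis$protein, cfg$mad_threshold, samples = lm_samples)
    if (length(feats) < 20) {
      feats <- names(sort(apply(analysis$protein$values[, lm_samples], 1,
                                stats::mad, na.rm = TRUE), decreasing = TRUE))[1:200]
    }
    cres <- consensus_cluster(analysis$protein, feats, samples = lm_samples,
                              k_range = 2:4, n_iter = cfg$consensus_iter,
                              seed = cfg$seed + 2)
    sel <- select_k(cres, override_k = 2)
    labels <- canonical_subtype_labels(
      sel$labels, subset_omics(analysis$protein, samples = lm_samples),
      metabolism_set = intersect(bundle$truth$metabolism_genes,
                                 feature_ids(analysis$protein))
    )
    subtype_by_patient <- stats::setNames(
      unname(labels), cl$patient_id[match(names(labels), cl$sample_id)]
    )
    write_tsv(data.frame(sample_id = names(labels), subtype = unname(labels)),
              file.path(cfg$outdir, "subtype_labels.tsv"))
    write_tsv(sel$report, file.path(cfg$outdir, "subtype_selection_report.tsv"))
    out$subtype <- list(result = cres, selection = sel, labels = labels,
                        by_patient = subtype_by_patient,
                        n_features = length(feats))
    log("stage subtype: %d MAD-selected features (> %g), k=2 consensus=%.3f",
        length(feats), cfg$mad_threshold, within_cluster_consensus(cres, 2))
    completed <- c(completed, "subtype")
  }

  ## splicing -------------------------------------------------------------
  if ("splicing" %in% stages) {
    filt <- filter_as_events(bundle$as_events)
    surv_scan <- suppressMessages(as_survival_scan(filt, cl))
    net <- factor_event_network(analysis$protein, bundle$truth$splicing_factors,
                                filt)
    write_tsv(filt$events, file.path(cfg$outdir, "as_filtered.tsv"))
    write_tsv(surv_scan$records, file.path(cfg$outdir, "as_survival.tsv"))
    write_tsv(net$edges, file.path(cfg$outdir, "factor_event_edges.tsv"))
    out$splicing <- list(filtered = filt, survival = surv_scan, network = net)
    log("stage splicing (fdr < 0.05, |dPSI| > 0.1): %d events pass, %d prognostic, %d network edges",
        nrow(filt$events), sum(surv_scan$records$prognosis != "ns"),
        nrow(net$edges))
    completed <- c(completed, "splicing")
  }

  ## biomarker ------------------------------------------------------------
  if ("biomarker" %in% stages) {
    subs <- if (!is.null(out$subtype)) out$subtype$by_patient else bundle$truth$subtype
    cl_sub <- attach_subtypes(cl, subs)
    prot_scan <- suppressMessages(
      protein_biomarker_scan(analysis$protein, cl_sub, policy = cfg$biomarker_policy)
    )
    phos_scan <- suppressMessages(
      phospho_biomarker_scan(analysis$phosphosite, bundle$site_annotation,
                             cl_sub, policy = cfg$biomarker_policy)
    )
    write_tsv(prot_scan$records, file.path(cfg$outdir, "biomarker_protein_trace.tsv"))
    write_tsv(phos_scan$records, file.path(cfg$outdir, "biomarker_phospho_trace.tsv"))
    write_tsv(data.frame(layer = c(rep("protein", length(prot_scan$passing)),
                                   rep("phosphosite", length(phos_scan$passing))),
                         feature = c(prot_scan$passing, phos_scan$passing)),
              file.path(cfg$outdir, "biomarker_final.tsv"))
    out$biomarker <- list(protein = prot_scan, phospho = phos_scan)
    log("stage biomarker (miss < %g, fc > %g/%g, p < %g, score > %g, logrank p < %g): %d protein + %d phospho pass",
        cfg$biomarker_policy$max_missing, cfg$biomarker_policy$protein_fc,
        cfg$biomarker_policy$phospho_fc, cfg$biomarker_policy$max_p,
        cfg$biomarker_policy$min_functional_score, cfg$biomarker_policy$max_logrank_p,
        length(prot_scan$passing), length(phos_scan$passing))
    completed <- c(completed, "biomarker")
  }

  ## survival -------------------------------------------------------------
  if ("survival" %in% stages) {
    subs <- if (!is.null(out$subtype)) out$subtype$by_patient else bundle$truth$subtype
    pat <- cl[cl$tissue == "LM", ]
    grp <- subs[pat$patient_id]
    lr <- logrank_test(pat$os_time[grp == "C1"], pat$os_event[grp == "C1"],
                       pat$os_time[grp == "C2"], pat$os_event[grp == "C2"])
    crs_high <- pat$crs >= 3
    lr_crs <- logrank_test(pat$os_time[crs_high], pat$os_event[crs_high],
                           pat$os_time[!crs_high], pat$os_event[!crs_high])
    write_tsv(data.frame(
      contrast = c("C1_vs_C2", "CRS_high_vs_low"),
      chisq = c(lr$statistic, lr_crs$statistic),
      p = c(lr$p_value, lr_crs$p_value)
    ), file.path(cfg$outdir, "survival_tests.tsv"))
    out$survival <- list(subtype = lr, crs = lr_crs)
    log("stage survival: C1 vs C2 logrank p=%.4g; CRS>=3 vs <3 p=%.4g",
        lr$p_value, lr_crs$p_value)
    completed <- c(completed, "survival")
  }

  out$bundle <- bundle
  invisible(out)
}
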