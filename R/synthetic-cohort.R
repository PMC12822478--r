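#' @title Synthetic multi-omics CRLM cohort with planted ground truth
#' @description Generates a paired N/T/LM cohort whose structure mirrors a
#'   TMT proteogenomic study: a cnv -> mrna -> protein -> phosphosite chain
#'   with attenuating cis effects, two LM proteomic subtypes (a metabolism
#'   block and an RNA-function block) with subtype-dependent survival,
#'   planted active kinases propagating to substrate phosphosites,
#'   intensity-dependent missingness, internal-reference (IRS) replicate
#'   columns, planted subtype-specific biomarkers and an rMATS-style
#'   alternative-splicing table with factor-driven events. Everything is
#'   deterministic given the seed, and every planted id is recorded in a
#'   truth manifest so recovery is testable.
#' @name synthetic-cohort
NULL

# Independent substream per generated component: adding one layer never
# perturbs another layer's draws.
stream_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * (seq_len(nchar(key)) + 7))
  as.integer((as.double(seed) * 131 + h * 1009) %% 2147483629)
}

with_stream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(stream_seed(seed, key))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the cohort shape of a 34-patient paired N/T/LM study
#' (102 clinical samples) with 8000 genes, target cis-effect Spearman
#' levels (0.6, 0.4, 0.25) for mrna/protein/phosphosite, two 300-gene
#' subtype blocks, five planted kinases, a C1-vs-C2 hazard ratio of 3 and
#' ~15% overall missingness in the MS layers.
#'
#' @param n_patients Patients; each contributes one N, one T and one LM sample.
#' @param n_genes Total genes.
#' @param n_metabolism,n_rna_function Subtype block sizes (C1-high
#'   metabolism genes, C2-high RNA-function genes; shifts apply to LM samples).
#' @param n_cis_genes Genes with a planted copy-number cis effect.
#' @param cis_targets Named vector `c(mrna=, protein=, phospho=)` of target
#'   Spearman correlations for the planted cis genes; must be strictly
#'   decreasing (or all zero for a null cohort).
#' @param tissue_shift log2 shift (at the mRNA level, propagating down the
#'   chain) for the planted LM-enriched / T-enriched gene sets.
#' @param n_lm_up,n_t_up Sizes of the planted LM-/T-enriched gene sets.
#' @param subtype_effect log2 protein shift of block genes in LM samples of
#'   the matching subtype (about two marginal protein SDs by default).
#' @param n_kinases,substrates_per_kinase,kinase_shift Planted LM-active
#'   kinases: each shifts its substrate phosphosites by `kinase_shift` log2
#'   units in LM samples. `n_null_kinases` inactive kinases pad the map.
#' @param n_null_kinases Inactive kinases in the substrate map.
#' @param phospho_sites_per_gene Mean phosphosites per gene (Poisson).
#' @param log_hr Log hazard ratio of subtype C1 vs C2 for overall survival.
#' @param base_median_os Median OS (days) of the C2 subtype.
#' @param censor_frac Approximate censoring fraction in the C2 subtype.
#' @param mcar_rate Completely-at-random missingness rate (protein/phospho).
#' @param mnar_mid,mnar_slope Logistic missing-not-at-random model on log2
#'   abundance: P(missing) = plogis((mnar_mid - abundance) * mnar_slope).
#' @param n_irs,sigma_irs IRS replicate columns (cohort mean profile plus
#'   N(0, sigma_irs) noise) appended to protein/phosphosite matrices.
#' @param n_as_events,n_as_planted,as_logit_delta AS event table size,
#'   planted subtype-differential events, and their logit-PSI shift.
#' @param n_splicing_factors,n_factor_edges Splicing-factor proteins and
#'   planted factor-driven AS events (one edge per driven event).
#' @param n_protein_markers,marker_shift Planted C1-LM-specific protein
#'   biomarkers and their log2 shift (C1-LM vs every other sample set).
#' @param marker_noise_sd Residual noise SD of planted biomarker features;
#'   markers emulate abundant, precisely quantified proteins whose TMT
#'   measurement noise is well below the proteome-wide residual.
#' @param n_phospho_markers,phospho_marker_shift Planted C1-vs-C2 (LM)
#'   phosphosite biomarkers with high functional scores.
#' @param seed Mandatory integer seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 34,
                             n_genes = 8000,
                             n_metabolism = 300,
                             n_rna_function = 300,
                             n_cis_genes = 500,
                             cis_targets = c(mrna = 0.6, protein = 0.4, phospho = 0.25),
                             tissue_shift = 2.8,
                             n_lm_up = 245,
                             n_t_up = 96,
                             subtype_effect = 2.6,
                             n_kinases = 5,
                             substrates_per_kinase = 15,
                             kinase_shift = 1,
                             n_null_kinases = 15,
                             phospho_sites_per_gene = 2,
                             log_hr = log(3),
                             base_median_os = 1095,
                             censor_frac = 0.3,
                             mcar_rate = 0.02,
                             mnar_mid = -2.8,
                             mnar_slope = 1.1,
                             n_irs = 3,
                             sigma_irs = 0.15,
                             n_as_events = 60,
                             n_as_planted = 15,
                             as_logit_delta = 1.5,
                             n_splicing_factors = 6,
                             n_factor_edges = 11,
                             n_protein_markers = 10,
                             marker_shift = 1.5,
                             marker_noise_sd = 0.5,
                             n_phospho_markers = 10,
                             phospho_marker_shift = 1.2,
                             seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  validate_synthetic_config(cfg)
}

#' Validate a synthetic cohort configuration
#' @param cfg List of configuration fields (see [synthetic_config()]).
#' @return The validated config, classed `synthetic_config`.
#' @export
validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 4, cfg$n_genes >= 10)
  rates <- c(cfg$censor_frac, cfg$mcar_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  reserved <- cfg$n_metabolism + cfg$n_rna_function + cfg$n_cis_genes +
    cfg$n_splicing_factors + cfg$n_protein_markers
  if (reserved > cfg$n_genes) {
    stop("infeasible config: block sizes + cis genes + factors + markers (",
         reserved, ") exceed n_genes (", cfg$n_genes, ")")
  }
  r <- cfg$cis_targets
  if (!all(c("mrna", "protein", "phospho") %in% names(r))) {
    stop("cis_targets needs named entries mrna, protein, phospho")
  }
  r <- r[c("mrna", "protein", "phospho")]
  if (!all(r == 0)) {
    if (!(r[1] > r[2] && r[2] > r[3] && r[3] > 0 && r[1] < 1)) {
      stop("infeasible cis_targets: need 1 > mrna > protein > phospho > 0 ",
           "(the chain cnv -> mrna -> protein -> phospho can only attenuate)")
    }
  }
  if (cfg$n_as_planted + cfg$n_factor_edges > cfg$n_as_events) {
    stop("infeasible config: planted + factor-driven AS events exceed n_as_events")
  }
  structure(cfg, class = "synthetic_config")
}

# Solve the noise chain so Pearson correlations of cnv with each layer hit
# the targets in expectation: mrna = a*cnv + e1, protein = b*mrna + e2,
# phospho = protein + e3, with sd(e1) = sd(e2) = 1 and sd(e3) solved.
solve_cis_chain <- function(targets, var_cnv) {
  r1 <- targets[["mrna"]]; r2 <- targets[["protein"]]; r3 <- targets[["phospho"]]
  if (r1 == 0 && r2 == 0 && r3 == 0) {
    return(list(a = 0, b = 0.7, sigma_phospho = 1.3))
  }
  a <- r1 / sqrt(1 - r1^2) / sqrt(var_cnv)
  b <- sqrt(r2^2 * (1 - r1^2) / (r1^2 - r2^2))
  var_protein <- b^2 / (1 - r1^2) + 1
  sigma_phospho <- sqrt(var_protein * (r2^2 / r3^2 - 1))
  list(a = a, b = b, sigma_phospho = sigma_phospho)
}

#' Generate a synthetic multi-omics cohort
#'
#' @param config A [synthetic_config()].
#' @return A `cohort_bundle` list: `cnv`, `mrna`, `protein`, `phosphosite`
#'   (omics matrices; protein/phosphosite carry IRS columns), `clinical`
#'   (data frame), `kinase_map`, `as_events`, `site_annotation`, `truth`
#'   (the manifest), `config`.
#' @export
generate_cohort <- function(config) {
  cfg <- validate_synthetic_config(config)
  seed <- cfg$seed

  ## ---- gene and sample bookkeeping -------------------------------------
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  idx <- 0
  take <- function(n) { out <- genes[idx + seq_len(n)]; idx <<- idx + n; out }
  metabolism_genes <- take(cfg$n_metabolism)
  rna_function_genes <- take(cfg$n_rna_function)
  cis_genes <- take(cfg$n_cis_genes)
  factor_genes <- take(cfg$n_splicing_factors)
  marker_genes <- take(cfg$n_protein_markers)
  null_pool <- genes[(idx + 1):cfg$n_genes]
  lm_up_genes <- utils::head(null_pool, cfg$n_lm_up)
  t_up_genes <- utils::head(setdiff(null_pool, lm_up_genes), cfg$n_t_up)

  patients <- sprintf("P%03d", seq_len(cfg$n_patients))
  tissues <- c("N", "T", "LM")
  samples <- as.vector(t(outer(patients, tissues, paste, sep = "_")))
  sample_patient <- rep(patients, each = 3)
  sample_tissue <- rep(tissues, times = cfg$n_patients)

  ## ---- patient-level truth: subtype and survival -----------------------
  # balanced prevalence: exactly half the patients per subtype (random which)
  subtype <- with_stream(seed, "subtype", {
    stats::setNames(sample(rep(c("C1", "C2"), length.out = cfg$n_patients)),
                    patients)
  })
  clinical <- with_stream(seed, "clinical", {
    lambda0 <- log(2) / cfg$base_median_os
    rate_death <- lambda0 * exp(cfg$log_hr * (subtype == "C1"))
    rate_censor <- lambda0 * cfg$censor_frac / (1 - cfg$censor_frac)
    t_death <- stats::rexp(cfg$n_patients, rate_death)
    t_cens <- stats::rexp(cfg$n_patients, rate_censor)
    os_time <- ceiling(pmin(t_death, t_cens))
    os_event <- as.integer(t_death <= t_cens)
    pfs_death <- t_death * stats::runif(cfg$n_patients, 0.4, 0.9)
    pfs_time <- ceiling(pmin(pfs_death, t_cens))
    pfs_event <- as.integer(pfs_death <= t_cens)
    crs <- sample(0:5, cfg$n_patients, replace = TRUE,
                  prob = c(0.05, 0.15, 0.25, 0.25, 0.2, 0.1))
    data.frame(
      patient_id = sample_patient,
      sample_id = samples,
      tissue = sample_tissue,
      crs = crs[match(sample_patient, patients)],
      os_time = os_time[match(sample_patient, patients)],
      os_event = os_event[match(sample_patient, patients)],
      pfs_time = pfs_time[match(sample_patient, patients)],
      pfs_event = pfs_event[match(sample_patient, patients)],
      stringsAsFactors = FALSE
    )
  })

  ## ---- cnv layer: per-patient gene states in {-1, 0, +1} ----------------
  state_probs <- c(0.3, 0.4, 0.3)
  var_cnv <- sum(state_probs * c(1, 0, 1))  # E[X^2], E[X] = 0
  chain <- solve_cis_chain(cfg$cis_targets, var_cnv)
  cnv_states <- with_stream(seed, "cnv", {
    matrix(sample(c(-1, 0, 1), cfg$n_genes * cfg$n_patients, replace = TRUE,
                  prob = state_probs),
           nrow = cfg$n_genes, dimnames = list(genes, patients))
  })
  cnv_vals <- matrix(0, cfg$n_genes, length(samples), dimnames = list(genes, samples))
  tumor <- sample_tissue != "N"
  cnv_vals[, tumor] <- cnv_states[, sample_patient[tumor]]

  ## ---- expression chain -------------------------------------------------
  is_cis <- genes %in% cis_genes
  a_vec <- ifelse(is_cis, chain$a, 0)
  tissue_delta <- matrix(0, cfg$n_genes, 3, dimnames = list(genes, tissues))
  tissue_delta[lm_up_genes, "LM"] <- cfg$tissue_shift
  tissue_delta[t_up_genes, "T"] <- cfg$tissue_shift

  mrna_core <- with_stream(seed, "mrna", {
    a_vec * cnv_vals + tissue_delta[, sample_tissue] +
      matrix(stats::rnorm(cfg$n_genes * length(samples)), cfg$n_genes)
  })

  sample_subtype <- subtype[sample_patient]
  is_lm <- sample_tissue == "LM"
  subtype_delta <- matrix(0, cfg$n_genes, length(samples), dimnames = list(genes, samples))
  subtype_delta[metabolism_genes, is_lm & sample_subtype == "C1"] <- cfg$subtype_effect
  subtype_delta[rna_function_genes, is_lm & sample_subtype == "C2"] <- cfg$subtype_effect
  subtype_delta[marker_genes, is_lm & sample_subtype == "C1"] <- cfg$marker_shift

  protein_core <- with_stream(seed, "protein", {
    noise <- matrix(stats::rnorm(cfg$n_genes * length(samples)), cfg$n_genes,
                    dimnames = list(genes, NULL))
    # planted biomarkers emulate abundant, precisely quantified proteins:
    # TMT measurement noise is intensity-dependent, so their residual is small
    noise[marker_genes, ] <- noise[marker_genes, ] * cfg$marker_noise_sd
    out <- chain$b * mrna_core + subtype_delta + noise
    # markers are protein-level effects, decoupled from their transcripts
    # (post-transcriptional regulation; cf. protein-only markers in tumors)
    out[marker_genes, ] <- subtype_delta[marker_genes, ] + noise[marker_genes, ]
    out
  })

  ## ---- phosphosite structure -------------------------------------------
  ph <- with_stream(seed, "phospho_structure", {
    n_sites <- stats::rpois(cfg$n_genes, cfg$phospho_sites_per_gene)
    names(n_sites) <- genes
    # guarantee enough sites for the kinase map and planted phospho markers
    n_kin_sites <- (cfg$n_kinases + cfg$n_null_kinases) * cfg$substrates_per_kinase
    need_site <- unique(c(marker_genes,
                          utils::head(null_pool, 2 * n_kin_sites + 50)))
    n_sites[need_site] <- pmax(n_sites[need_site], 1L)
    site_gene <- rep(genes, n_sites)
    residue <- sample(c("S", "T", "Y"), length(site_gene), replace = TRUE,
                      prob = c(0.8, 0.15, 0.05))
    pos <- unlist(lapply(n_sites[n_sites > 0], function(k) sample(1:999, k)),
                  use.names = FALSE)
    list(site_gene = site_gene,
         site_id = paste0(site_gene, "_", residue, pos))
  })
  site_gene <- ph$site_gene
  site_ids <- ph$site_id
  n_sites_total <- length(site_ids)

  # planted kinases: substrates drawn from sites on null-pool genes
  kin <- with_stream(seed, "kinase_map", {
    eligible <- which(site_gene %in% setdiff(null_pool, c(lm_up_genes, t_up_genes)))
    n_active <- cfg$n_kinases * cfg$substrates_per_kinase
    picked <- sample(eligible, n_active + cfg$n_null_kinases * cfg$substrates_per_kinase)
    active_sites <- picked[seq_len(n_active)]
    null_sites <- picked[-seq_len(n_active)]
    map <- c(
      split(site_ids[active_sites],
            rep(sprintf("KIN_ACT%02d", seq_len(cfg$n_kinases)),
                each = cfg$substrates_per_kinase)),
      split(site_ids[null_sites],
            rep(sprintf("KIN_NULL%02d", seq_len(cfg$n_null_kinases)),
                each = cfg$substrates_per_kinase))
    )
    list(map = map, active_site_idx = active_sites)
  })

  # phospho biomarkers: C1-vs-C2 (LM) shifted sites on null genes, not
  # already kinase substrates
  pmark_idx <- with_stream(seed, "phospho_markers", {
    eligible <- setdiff(which(site_gene %in% marker_genes), kin$active_site_idx)
    if (length(eligible) < cfg$n_phospho_markers) {
      eligible <- union(eligible,
                        setdiff(which(site_gene %in% null_pool), kin$active_site_idx))
    }
    sort(sample(eligible, cfg$n_phospho_markers))
  })

  phospho_core <- with_stream(seed, "phospho", {
    noise <- matrix(stats::rnorm(n_sites_total * length(samples),
                                 sd = chain$sigma_phospho), n_sites_total)
    noise[pmark_idx, ] <- noise[pmark_idx, ] *
      (cfg$marker_noise_sd / chain$sigma_phospho)
    v <- protein_core[site_gene, , drop = FALSE] + noise
    rownames(v) <- site_ids
    # kinase activity shift in LM samples
    kin_sites <- match(unlist(kin$map[grep("^KIN_ACT", names(kin$map))], use.names = FALSE),
                       site_ids)
    v[kin_sites, is_lm] <- v[kin_sites, is_lm] + cfg$kinase_shift
    v[pmark_idx, is_lm & sample_subtype == "C1"] <-
      v[pmark_idx, is_lm & sample_subtype == "C1"] + cfg$phospho_marker_shift
    v
  })

  ## ---- abundance offsets, missingness, IRS, sample loading --------------
  offs <- with_stream(seed, "abundance", {
    mu_gene <- stats::rnorm(cfg$n_genes, 0, 1.5)
    names(mu_gene) <- genes
    # planted biomarkers are high-abundance so they clear missingness gates
    mu_gene[marker_genes] <- abs(mu_gene[marker_genes]) + 1.5
    mu_site <- mu_gene[site_gene] + stats::rnorm(n_sites_total, 0, 0.5)
    mu_site[pmark_idx] <- abs(mu_site[pmark_idx]) + 1.5
    list(gene = mu_gene, site = stats::setNames(mu_site, site_ids))
  })

  mrna_abund <- mrna_core + offs$gene
  protein_abund <- protein_core + offs$gene
  phospho_abund <- phospho_core + offs$site

  apply_missing <- function(abund, key) {
    with_stream(seed, key, {
      p_mnar <- stats::plogis((cfg$mnar_mid - abund) * cfg$mnar_slope)
      miss <- matrix(stats::runif(length(abund)) < p_mnar, nrow(abund))
      miss <- miss | matrix(stats::runif(length(abund)) < cfg$mcar_rate, nrow(abund))
      out <- abund
      out[miss] <- NA_real_
      out
    })
  }
  protein_obs <- apply_missing(protein_abund, "missing_protein")
  phospho_obs <- apply_missing(phospho_abund, "missing_phospho")
  mrna_obs <- with_stream(seed, "missing_mrna", {
    miss <- matrix(stats::runif(length(mrna_abund)) < 0.01, nrow(mrna_abund))
    out <- mrna_abund; out[miss] <- NA_real_; out
  })

  add_irs <- function(obs, abund, key) {
    if (cfg$n_irs < 1) return(obs)
    with_stream(seed, key, {
      profile <- rowMeans(abund)
      irs <- profile + matrix(stats::rnorm(nrow(abund) * cfg$n_irs, 0, cfg$sigma_irs),
                              nrow(abund))
      colnames(irs) <- sprintf("IRS_%d", seq_len(cfg$n_irs))
      cbind(obs, irs)
    })
  }
  protein_obs <- add_irs(protein_obs, protein_abund, "irs_protein")
  phospho_obs <- add_irs(phospho_obs, phospho_abund, "irs_phospho")

  # per-sample loading offsets (what median normalization removes)
  loading <- with_stream(seed, "loading", {
    n_tot <- length(samples) + cfg$n_irs
    stats::rnorm(n_tot, 0, 0.3)
  })
  protein_obs <- sweep(protein_obs, 2, loading[seq_len(ncol(protein_obs))], "+")
  phospho_obs <- sweep(phospho_obs, 2, loading[seq_len(ncol(phospho_obs))], "+")
  mrna_obs <- sweep(mrna_obs, 2, loading[seq_len(ncol(mrna_obs))], "+")

  ## ---- alternative-splicing table ---------------------------------------
  as_bits <- with_stream(seed, "as_events", {
    n_ev <- cfg$n_as_events
    ev_gene <- sample(null_pool, n_ev)
    ev_type <- sample(AS_EVENT_TYPES, n_ev, replace = TRUE,
                      prob = c(0.1, 0.05, 0.15, 0.05, 0.65))
    ev_id <- sprintf("AS%04d_%s", seq_len(n_ev), ev_type)
    as_samples <- samples[sample_tissue %in% c("T", "LM")]
    as_sub <- subtype[sub("_(T|LM)$", "", as_samples)]
    as_is_lm <- grepl("_LM$", as_samples)
    base <- stats::rnorm(n_ev, 0, 0.8)
    logit <- matrix(base, n_ev, length(as_samples)) +
      matrix(stats::rnorm(n_ev * length(as_samples), 0, 0.6), n_ev)
    planted <- seq_len(cfg$n_as_planted)
    # planted subtype-differential events: logit shift in C1 LM samples
    logit[planted, as_is_lm & as_sub == "C1"] <-
      logit[planted, as_is_lm & as_sub == "C1"] + cfg$as_logit_delta
    # factor-driven events: PSI logit tracks a splicing factor's protein
    # level, on top of a subtype shift so these events survive the
    # subtype-differential filter that defines the network's event universe
    edge_events <- cfg$n_as_planted + seq_len(cfg$n_factor_edges)
    edge_factor <- factor_genes[1 + (seq_len(cfg$n_factor_edges) - 1) %% cfg$n_splicing_factors]
    edge_sign <- rep(c(1, -1), length.out = cfg$n_factor_edges)
    fac_prot <- protein_core[edge_factor, as_samples, drop = FALSE]
    fac_z <- t(scale(t(fac_prot)))
    logit[edge_events, ] <- 0.8 * (edge_sign * fac_z) +
      matrix(cfg$as_logit_delta * (as_is_lm & as_sub == "C1"),
             cfg$n_factor_edges, length(as_samples), byrow = TRUE) +
      matrix(stats::rnorm(cfg$n_factor_edges * length(as_samples), 0, 0.45),
             cfg$n_factor_edges)
    psi <- stats::plogis(logit)
    dimnames(psi) <- list(ev_id, as_samples)
    # rMATS-style columns from the C1-vs-C2 LM contrast
    lm_c1 <- as_is_lm & as_sub == "C1"; lm_c2 <- as_is_lm & as_sub == "C2"
    ild <- rowMeans(psi[, lm_c1, drop = FALSE]) - rowMeans(psi[, lm_c2, drop = FALSE])
    pvals <- vapply(seq_len(n_ev), function(i) {
      suppressWarnings(stats::wilcox.test(psi[i, lm_c1], psi[i, lm_c2])$p.value)
    }, numeric(1))
    events <- data.frame(
      event_id = ev_id, gene = ev_gene, event_type = ev_type,
      inc_level_difference = ild,
      fdr = stats::p.adjust(pvals, "BH"),
      stringsAsFactors = FALSE
    )
    list(
      table = structure(list(events = events, psi = psi), class = "as_event_table"),
      planted_events = ev_id[planted],
      edges = data.frame(factor = edge_factor, event_id = ev_id[edge_events],
                         sign = edge_sign, stringsAsFactors = FALSE)
    )
  })

  ## ---- site annotation ---------------------------------------------------
  annotation <- with_stream(seed, "annotation", {
    score <- stats::runif(n_sites_total)
    score[pmark_idx] <- stats::runif(cfg$n_phospho_markers, 0.6, 0.95)
    data.frame(
      site_id = site_ids,
      functional_score = score,
      localization_class = sample(c("I", "II"), n_sites_total,
                                  replace = TRUE, prob = c(0.85, 0.15)),
      stringsAsFactors = FALSE
    )
  })

  truth <- list(
    subtype = subtype,
    cis_genes = cis_genes,
    metabolism_genes = metabolism_genes,
    rna_function_genes = rna_function_genes,
    lm_up_genes = lm_up_genes,
    t_up_genes = t_up_genes,
    active_kinases = grep("^KIN_ACT", names(kin$map), value = TRUE),
    protein_markers = marker_genes,
    phospho_markers = site_ids[pmark_idx],
    splicing_factors = factor_genes,
    as_subtype_events = as_bits$planted_events,
    factor_event_edges = as_bits$edges,
    log_hr = cfg$log_hr,
    chain = chain
  )

  bundle <- list(
    cnv = omics_matrix(cnv_vals, "cnv", is_normalized = TRUE),
    mrna = omics_matrix(mrna_obs, "mrna", is_normalized = FALSE),
    protein = omics_matrix(protein_obs, "protein", is_normalized = FALSE),
    phosphosite = omics_matrix(phospho_obs, "phosphosite", is_normalized = FALSE),
    clinical = validate_clinical(clinical),
    kinase_map = kin$map,
    as_events = as_bits$table,
    site_annotation = annotation,
    truth = truth,
    config = cfg
  )
  class(bundle) <- "cohort_bundle"
  check_truth_manifest(bundle)
  bundle
}

# every planted id must exist in the generated matrices
check_truth_manifest <- function(bundle) {
  tr <- bundle$truth
  stopifnot(
    all(tr$cis_genes %in% feature_ids(bundle$cnv)),
    all(tr$protein_markers %in% feature_ids(bundle$protein)),
    all(tr$phospho_markers %in% feature_ids(bundle$phosphosite)),
    all(tr$splicing_factors %in% feature_ids(bundle$protein)),
    all(tr$as_subtype_events %in% bundle$as_events$events$event_id),
    all(tr$factor_event_edges$event_id %in% bundle$as_events$events$event_id),
    all(unlist(bundle$kinase_map) %in% feature_ids(bundle$phosphosite))
  )
  invisible(bundle)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d patients, %d samples, seed %d\n",
              x$config$n_patients, nrow(x$clinical), x$config$seed))
  invisible(x)
}

#' Summarize a generated cohort
#'
#' @param bundle A `cohort_bundle` from [generate_cohort()].
#' @return Data frame with sample counts per tissue and subtype, feature
#'   counts per layer and per-layer missingness fractions (IRS columns
#'   excluded from the missingness denominator).
#' @export
cohort_summary <- function(bundle) {
  if (is.null(bundle$clinical) || nrow(bundle$clinical) == 0) {
    stop("empty cohort bundle")
  }
  cl <- bundle$clinical
  layer_missing <- function(m) {
    keep <- setdiff(sample_ids(m), grep("^IRS_", sample_ids(m), value = TRUE))
    mean(is.na(m$values[, keep, drop = FALSE]))
  }
  layers <- c("cnv", "mrna", "protein", "phosphosite")
  data.frame(
    metric = c("n_samples", "n_patients",
               paste0("n_tissue_", TISSUE_CODES),
               paste0("n_subtype_", c("C1", "C2")),
               paste0("n_features_", layers),
               paste0("missing_frac_", layers)),
    value = c(nrow(cl), length(unique(cl$patient_id)),
              as.vector(table(cl$tissue)[TISSUE_CODES]),
              as.vector(table(factor(bundle$truth$subtype, c("C1", "C2")))),
              vapply(bundle[layers], function(m) nrow(m$values), numeric(1)),
              vapply(bundle[layers], layer_missing, numeric(1)))
  )
}

#' Write all cohort artifacts to a directory
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_omics_matrix(bundle$cnv, p("cnv.tsv"))
  write_omics_matrix(bundle$mrna, p("mrna.tsv"))
  write_omics_matrix(bundle$protein, p("protein.tsv"))
  write_omics_matrix(bundle$phosphosite, p("phosphosite.tsv"))
  write_clinical(bundle$clinical, p("clinical.tsv"))
  write_kinase_substrate_map(bundle$kinase_map, p("kinase_substrate_map.tsv"))
  write_as_events(bundle$as_events, p("as_events.tsv"))
  write_site_annotation(bundle$site_annotation, p("site_annotation.tsv"))
  tr <- bundle$truth
  truth_df <- rbind(
    data.frame(kind = "subtype", id = names(tr$subtype), value = unname(tr$subtype)),
    data.frame(kind = "cis_gene", id = tr$cis_genes, value = ""),
    data.frame(kind = "metabolism_gene", id = tr$metabolism_genes, value = ""),
    data.frame(kind = "rna_function_gene", id = tr$rna_function_genes, value = ""),
    data.frame(kind = "lm_up_gene", id = tr$lm_up_genes, value = ""),
    data.frame(kind = "t_up_gene", id = tr$t_up_genes, value = ""),
    data.frame(kind = "active_kinase", id = tr$active_kinases, value = ""),
    data.frame(kind = "protein_marker", id = tr$protein_markers, value = ""),
    data.frame(kind = "phospho_marker", id = tr$phospho_markers, value = ""),
    data.frame(kind = "splicing_factor", id = tr$splicing_factors, value = ""),
    data.frame(kind = "as_subtype_event", id = tr$as_subtype_events, value = ""),
    data.frame(kind = "factor_event_edge", id = tr$factor_event_edges$event_id,
               value = paste0(tr$factor_event_edges$factor, ":",
                              tr$factor_event_edges$sign)),
    data.frame(kind = "log_hr", id = "C1_vs_C2", value = as.character(tr$log_hr))
  )
  write_tsv(truth_df, p("truth_manifest.tsv"))
  invisible(dir)
}
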