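test_that("the generator is deterministic and layer-stable given the seed", {
  cfg <- small_cohort_config(101, n_patients = 8, n_genes = 300,
                             n_metabolism = 20, n_rna_function = 20,
                             n_cis_genes = 40, n_lm_up = 20, n_t_up = 10)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$protein$values, b$protein$values)
  expect_identical(a$as_events$psi, b$as_events$psi)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  # independent substreams: a different AS table size must not perturb the
  # expression layers
  cfg2 <- small_cohort_config(101, n_patients = 8, n_genes = 300,
                              n_metabolism = 20, n_rna_function = 20,
                              n_cis_genes = 40, n_lm_up = 20, n_t_up = 10,
                              n_as_events = 30, n_as_planted = 5,
                              n_factor_edges = 6)
  c <- generate_cohort(cfg2)
  expect_identical(a$protein$values, c$protein$values)
})

test_that("the default-shaped cohort matches the paired N/T/LM design", {
  cfg <- small_cohort_config(102, n_patients = 34, n_genes = 400,
                             n_metabolism = 20, n_rna_function = 20,
                             n_cis_genes = 40, n_lm_up = 20, n_t_up = 10)
  b <- generate_cohort(cfg)
  sm <- cohort_summary(b)
  val <- function(metric) sm$value[sm$metric == metric]
  expect_equal(val("n_samples"), 102)  # 34 patients x (N, T, LM)
  expect_equal(val("n_patients"), 34)
  expect_equal(val("n_tissue_LM"), 34)
  miss <- sm$value[startsWith(sm$metric, "missing_frac")]
  expect_true(all(miss >= 0 & miss <= 1))
  expect_error(cohort_summary(list(clinical = NULL)), "empty")
})

test_that("infeasible configurations raise explicit errors", {
  expect_error(synthetic_config(seed = 1,
                                cis_targets = c(mrna = 0.4, protein = 0.6, phospho = 0.2)),
               "infeasible cis_targets")
  expect_error(synthetic_config(seed = 1, n_genes = 100, n_cis_genes = 200),
               "exceed n_genes")
  expect_error(synthetic_config(n_patients = 10, n_genes = 100), "seed")
})

test_that("cis-effect attenuation ordering holds across layers", {
  b <- generate_cohort(small_cohort_config(103, n_patients = 30))
  tsamp <- tissue_samples(b$clinical, "T")
  cis <- b$truth$cis_genes
  sg <- site_to_gene(feature_ids(b$phosphosite))
  mean_abs_rho <- function(m, map_sites = FALSE) {
    vals <- vapply(cis, function(g) {
      x <- b$cnv$values[g, tsamp]
      if (map_sites) {
        idx <- which(sg == g)
        if (!length(idx)) return(NA_real_)
        mean(vapply(idx, function(i) {
          r <- spearman_corr(x, b$phosphosite$values[i, tsamp])$rho
          if (is.na(r)) 0 else abs(r)
        }, numeric(1)))
      } else {
        r <- spearman_corr(x, m$values[g, tsamp])$rho
        if (is.na(r)) NA_real_ else abs(r)
      }
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  r_mrna <- mean_abs_rho(b$mrna)
  r_prot <- mean_abs_rho(b$protein)
  r_phos <- mean_abs_rho(NULL, map_sites = TRUE)
  expect_gt(r_mrna, r_prot)
  expect_gt(r_prot, r_phos)
  # empirical medians near the configured targets
  expect_lt(abs(r_mrna - 0.6), 0.1)
  expect_lt(abs(r_prot - 0.4), 0.1)
})

test_that("IRS replicates are tightly correlated and survival tracks the hazard", {
  b <- generate_cohort(small_cohort_config(104, n_patients = 40))
  norm <- suppressMessages(normalize_log2_median(b$protein))
  irs <- grep("^IRS_", sample_ids(norm), value = TRUE)
  cm <- irs_reproducibility(norm, irs)
  expect_gt(min(cm[upper.tri(cm)]), 0.95)
  # KM median OS of C1 is below C2 when the planted log-HR is positive
  cl <- b$clinical[b$clinical$tissue == "LM", ]
  grp <- b$truth$subtype[cl$patient_id]
  km1 <- km_curve(cl$os_time[grp == "C1"], cl$os_event[grp == "C1"])
  km2 <- km_curve(cl$os_time[grp == "C2"], cl$os_event[grp == "C2"])
  expect_lt(km_median(km1), km_median(km2))
})

test_that("a zero-effect cohort is null-calibrated at every stage", {
  b <- generate_cohort(null_cohort_config(105))
  layers <- normalized_layers(b)
  cl <- b$clinical
  d <- suppressMessages(differential_table(
    layers$protein, tissue_samples(cl, "LM"), tissue_samples(cl, "T"),
    paired = TRUE, patients = patient_map(cl)
  ))
  n <- nrow(d$records)
  # raw p uniform: ~5% below 0.05; BH keeps the q<0.05 count at or under that
  expect_lt(abs(mean(d$records$p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  expect_lte(mean(d$records$q < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})
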