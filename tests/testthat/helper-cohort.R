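# Shared small cohort configurations for module tests. Planted fractions are
# kept close to the default config's proportions so per-sample median
# normalization behaves as it does at full scale.

small_cohort_config <- function(seed, ...) {
  args <- utils::modifyList(list(
    n_patients = 20, n_genes = 2000,
    n_metabolism = 80, n_rna_function = 80,
    n_cis_genes = 200, n_lm_up = 100, n_t_up = 50,
    seed = seed
  ), list(...))
  do.call(synthetic_config, args)
}

# Null cohort: no planted effects anywhere.
null_cohort_config <- function(seed, ...) {
  args <- utils::modifyList(list(
    n_patients = 20, n_genes = 1000,
    n_metabolism = 0, n_rna_function = 0,
    n_cis_genes = 0,
    cis_targets = c(mrna = 0, protein = 0, phospho = 0),
    tissue_shift = 0, n_lm_up = 0, n_t_up = 0,
    subtype_effect = 0, kinase_shift = 0,
    log_hr = 0, marker_shift = 0, phospho_marker_shift = 0,
    n_protein_markers = 0, n_phospho_markers = 0,
    as_logit_delta = 0,
    seed = seed
  ), list(...))
  do.call(synthetic_config, args)
}

normalized_layers <- function(bundle) {
  list(
    cnv = bundle$cnv,
    mrna = drop_irs(suppressMessages(normalize_log2_median(bundle$mrna))),
    protein = drop_irs(suppressMessages(normalize_log2_median(bundle$protein))),
    phosphosite = drop_irs(suppressMessages(normalize_log2_median(bundle$phosphosite)))
  )
}

tissue_samples <- function(clinical, tissue) {
  clinical$sample_id[clinical$tissue == tissue]
}

patient_map <- function(clinical) {
  stats::setNames(clinical$patient_id, clinical$sample_id)
}

# tiny omics matrix builder for unit tests
toy_matrix <- function(values, layer = "protein", normalized = TRUE,
                       features = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(features)) features <- sprintf("F%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(features, samples)
  omics_matrix(values, layer, is_normalized = normalized)
}
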