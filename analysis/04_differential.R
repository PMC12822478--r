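#!/usr/bin/env Rscript
# Layer-aware differential testing LM vs T (paired signed-rank within
# patient), the per-layer fold-change/p filters (mrna 1.5, protein 1.2,
# phosphosite 1.5, all at p < 0.05), and pathway over-representation of the
# filtered protein features against the quantified universe.

library(crlmomics)

clinical <- load_clinical("results/cohort/clinical.tsv")
patients <- setNames(clinical$patient_id, clinical$sample_id)
lm <- clinical$sample_id[clinical$tissue == "LM"]
tt <- clinical$sample_id[clinical$tissue == "T"]
policy <- threshold_policy()

all_filtered <- list()
for (layer in c("mrna", "protein", "phosphosite")) {
  m <- load_omics_matrix(sprintf("results/%s_normalized.tsv", layer), layer)
  d <- differential_table(m, lm, tt, paired = TRUE, patients = patients)
  write_tsv(d$records, sprintf("results/diff_%s.tsv", layer))
  f <- layer_threshold_filter(d$records, policy)
  all_filtered[[layer]] <- f
  cat(sprintf("%s: %d/%d features pass FC > %s & p < %g (%d up in LM, %d up in T)\n",
              layer, nrow(f), nrow(d$records),
              policy$fold_change[[layer]], policy$max_p,
              sum(f$direction > 0), sum(f$direction < 0)))
}
write_tsv(do.call(rbind, all_filtered), "results/diff_filtered.tsv")

sets <- load_gene_sets("results/gene_sets.gmt")
prot <- load_omics_matrix("results/protein_normalized.tsv", "protein")
ora <- pathway_ora(all_filtered$protein$feature, feature_ids(prot), sets)
write_tsv(ora[, names(ora) != "members"], "results/ora_protein.tsv")
cat("\ntop enriched sets among differential proteins:\n")
print(head(ora[, c("set", "overlap", "set_size", "p", "q")], 4), row.names = FALSE)
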