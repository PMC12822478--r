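#!/usr/bin/env Rscript
# Kinase-substrate enrichment analysis: per-site paired LM-vs-T contrasts
# (median per-patient log2 difference) aggregated over each kinase's
# annotated substrates into the substrate-set z-score, with the full
# kinase-substrate evidence table for the significant kinases.

library(crlmomics)

phospho <- load_omics_matrix("results/phosphosite_normalized.tsv", "phosphosite")
clinical <- load_clinical("results/cohort/clinical.tsv")
map <- load_kinase_substrate_map("results/cohort/kinase_substrate_map.tsv")
patients <- setNames(clinical$patient_id, clinical$sample_id)
lm <- clinical$sample_id[clinical$tissue == "LM"]
tt <- clinical$sample_id[clinical$tissue == "T"]

contrast <- site_contrast(phospho, lm, tt, paired = TRUE, patients = patients)
res <- ksea_scores(contrast, map)
write_tsv(res$activities, "results/kinase_activities.tsv")
cat(sprintf("%d kinases scored over %d quantified sites (background sd %.2f)\n",
            nrow(res$activities), res$background["n"], res$background["sd"]))
sig <- res$activities[res$activities$q < 0.05, ]
cat(sprintf("%d kinases differentially active at q < 0.05:\n", nrow(sig)))
print(sig[, c("kinase", "z", "q", "m", "mean_log2fc")], row.names = FALSE)

site_diff <- load_omics_matrix("results/phosphosite_normalized.tsv", "phosphosite")
diff_rec <- utils::read.delim("results/diff_phosphosite.tsv")
evid <- substrate_annotation(res$activities, map, diff_rec)
write_tsv(evid, "results/kinase_substrate_evidence.tsv")
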