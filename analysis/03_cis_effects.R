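#!/usr/bin/env Rscript
# Copy-number cis-effect scans: per-gene Spearman correlation of CNV with
# mRNA, protein and phosphosite abundance in T and in LM samples, BH within
# layer, and the multi-layer significance classification. The expected
# picture is the dosage-attenuation gradient: most cis effects visible at
# the transcript level, fewer at the protein level, fewest at phosphosites.

library(crlmomics)

cnv <- load_omics_matrix("results/cohort/cnv.tsv", "cnv")
mrna <- load_omics_matrix("results/mrna_normalized.tsv", "mrna")
protein <- load_omics_matrix("results/protein_normalized.tsv", "protein")
phospho <- load_omics_matrix("results/phosphosite_normalized.tsv", "phosphosite")
clinical <- load_clinical("results/cohort/clinical.tsv")

for (tissue in c("T", "LM")) {
  samples <- clinical$sample_id[clinical$tissue == tissue]
  scans <- cis_scan_all_layers(cnv, mrna, protein, phospho, samples)
  recs <- do.call(rbind, lapply(scans, function(s) s$records))
  recs$tissue <- tissue
  write_tsv(recs, sprintf("results/cis_records_%s.tsv", tissue))
  venn <- classify_cis_venn(scans)
  write_tsv(venn$per_gene, sprintf("results/cis_venn_%s.tsv", tissue))
  counts <- vapply(scans, function(s) sum(s$records$significant), numeric(1))
  cat(sprintf("%s samples: significant cis genes (q < 0.05) mrna=%d protein=%d phosphosite=%d\n",
              tissue, counts["mrna"], counts["protein"], counts["phosphosite"]))
}

# genome-wide transcript-protein concordance
mp <- mrna_protein_correlation(mrna, protein,
                               samples = clinical$sample_id[clinical$tissue != "N"])
cat(sprintf("median mRNA-protein Spearman rho = %.2f over %d genes\n",
            median(mp$rho, na.rm = TRUE), nrow(mp)))
write_tsv(mp, "results/mrna_protein_correlation.tsv")
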