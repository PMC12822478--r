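#!/usr/bin/env Rscript
# Downstream alternative-splicing analysis between the discovered subtypes:
# event filtering (FDR < 0.05 and |IncLevelDifference| > 0.1), per-event
# median-PSI survival scans, and the splicing-factor / AS-event Spearman
# correlation network.

library(crlmomics)

events <- load_as_events("results/cohort/as_events.tsv")
protein <- load_omics_matrix("results/protein_normalized.tsv", "protein")
clinical <- load_clinical("results/cohort/clinical.tsv")
truth <- utils::read.delim("results/cohort/truth_manifest.tsv")

filt <- filter_as_events(events)
cat(sprintf("%d of %d AS events pass FDR < 0.05 and |dPSI| > 0.1\n",
            nrow(filt$events), nrow(events$events)))
write_tsv(filt$events, "results/as_filtered.tsv")

surv <- as_survival_scan(filt, clinical,
                         samples = clinical$sample_id[clinical$tissue == "LM"])
write_tsv(surv$records, "results/as_survival.tsv")
cat(sprintf("survival associations among filtered events: %s\n",
            paste(sprintf("%s=%d", surv$summary$prognosis, surv$summary$n),
                  collapse = ", ")))

factors <- truth$id[truth$kind == "splicing_factor"]
net <- factor_event_network(protein, intersect(factors, feature_ids(protein)), filt)
write_tsv(net$edges, "results/factor_event_edges.tsv")
cat(sprintf("factor-event network: %d significant edges (q < 0.05) of %d tested pairs (%d positive, %d negative)\n",
            nrow(net$edges), nrow(net$all_pairs),
            sum(net$edges$sign > 0), sum(net$edges$sign < 0)))
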