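#!/usr/bin/env Rscript
# Generate the synthetic organ RNA-capture study: per organ, two +UV and one
# pooled -UV capture sample for both the poly(A) (eRIC) and non-poly(A)
# assays, plus duplicate total-proteome inputs, with known ground truth.
# Writes the quant table, sample sheet, truth table and annotation catalog.

library(ricproteo)

seed <- 20260920L
dir.create("results/simulated", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
sim <- simulate_eric_experiment(cfg)
catalog <- simulate_annotations(cfg, sim$truth)

write_quant_table(sim$quant, "results/simulated/quant.tsv",
                  "results/simulated/sample_sheet.tsv")
write_annotation_table(catalog, "results/simulated/annotations.tsv")
write_rna_content(simulated_rna_content(cfg$tissues),
                  "results/simulated/rna_content.tsv")
truth <- sim$truth$table
truth <- cbind(truth, sim$truth$log2fc[truth$protein, ])
names(truth)[4:6] <- paste0("true_log2fc_", colnames(sim$truth$log2fc))
write.table(truth, "results/simulated/ground_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("simulated %d proteins x %d samples (%.1f%% cells missing); ",
                nrow(sim$quant$intensity), ncol(sim$quant$intensity),
                100 * mean(is.na(sim$quant$intensity))),
        sprintf("%d true RBPs (%s)", sum(truth$is_rbp),
                paste(names(table(truth$binder_type[truth$is_rbp])),
                      table(truth$binder_type[truth$is_rbp]),
                      collapse = ", ", sep = "=")))
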