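#!/usr/bin/env Rscript
# Differential +UV vs -UV enrichment per (organ, assay): peptide filter,
# variance-stabilizing normalization with per-(tissue, condition) strata,
# per-protein linear model, empirical-Bayes moderated t-test, BH correction
# and hit/candidate calling at FDR < 0.05 & FC > 2 / FDR < 0.2 & FC > 1.5.

library(ricproteo)

quant <- read_quant_table("results/simulated/quant.tsv",
                          "results/simulated/sample_sheet.tsv")
thr <- rp_thresholds()
dir.create("results/differential", showWarnings = FALSE, recursive = TRUE)

for (assay in c("eric", "nonpolya_ric")) {
  for (tissue in unique(quant$samples$tissue)) {
    tab <- suppressWarnings(
      differential_enrichment(quant, thr, tissue = tissue, assay = assay))
    mod <- attr(tab, "moderation")
    write_differential_table(
      tab[, c("protein", "log2fc", "t_mod", "p_value", "fdr", "enrich_class",
              "n_unique_peptides")],
      sprintf("results/differential/%s_%s.tsv", assay, tissue))
    message(sprintf(
      "%s / %s: %d hits, %d candidates of %d proteins (prior d0 = %.2f, s0^2 = %.4f)",
      assay, tissue, sum(tab$enrich_class == "hit"),
      sum(tab$enrich_class == "candidate"), nrow(tab), mod$d0, mod$s0_sq))
  }
}

# replicate concordance of the +UV capture samples on the glog2 scale
eric_plus <- quant$samples$assay == "eric" & quant$samples$condition == "plusUV"
vst <- suppressWarnings(
  variance_stabilizing_transform(quant$intensity[, eric_plus]))
ids <- split(quant$samples$sample_id[eric_plus],
             quant$samples$tissue[eric_plus])
pairs <- do.call(rbind, lapply(ids, function(v) data.frame(s1 = v[1],
                                                           s2 = v[2])))
cors <- replicate_correlation(vst$mat, pairs)
write.table(cors, "results/differential/replicate_correlation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("replicate Pearson r: ",
        paste(sprintf("%.3f", cors$r), collapse = ", "))
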