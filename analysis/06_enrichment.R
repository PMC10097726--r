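#!/usr/bin/env Rscript
# Annotation enrichment: nucleotide-binding domain and cofactor
# overrepresentation among enzyme-RBPs (two-sided Fisher, BH-corrected),
# catalytic-type profiles (one-tailed, uncorrected, flagged as such), and
# per-pathway RBP fractions per organ.

library(ricproteo)

catalog <- read_annotation_table("results/simulated/annotations.tsv")
atlas <- read_atlas_table("results/atlas/binding_atlas.tsv")
quant <- read_quant_table("results/simulated/quant.tsv",
                          "results/simulated/sample_sheet.tsv")
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)

hit_sets <- atlas_hit_sets(atlas)
any_hit <- unique(unlist(hit_sets, use.names = FALSE))
enriched_any <- unique(unlist(c(
  atlas_hit_sets(atlas, class_filter = c("hit", "candidate")),
  atlas_hit_sets(atlas, class_filter = c("hit", "candidate"),
                 side = "nonpolya")), use.names = FALSE))
input_cols <- quant$samples$assay == "input"
input_detected <- rownames(quant$intensity)[
  rowSums(!is.na(quant$intensity[, input_cols, drop = FALSE])) > 0L]

cofac <- cofactor_domain_enrichment(any_hit, enriched_any, input_detected,
                                    catalog)
write.table(cofac, "results/enrichment/cofactor_domain_enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
sig <- cofac[cofac$fdr < 0.05, ]
message(nrow(sig), " of ", nrow(cofac),
        " domain/cofactor categories enriched at FDR < 0.05",
        if (nrow(sig) > 0)
          paste0(" (", paste(sig$category, collapse = ", "), ")") else "")

enz <- catalog$protein[catalog$protein_class ==
                         "metabolite interconversion enzyme"]
rbp_enz <- intersect(enz, any_hit)
other_enz <- intersect(enz, setdiff(input_detected, enriched_any))
cat_prof <- catalytic_class_profile(rbp_enz, other_enz, catalog)
write.table(cat_prof, "results/enrichment/catalytic_class_profile.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("catalytic types among enzyme-RBPs: ",
        paste(cat_prof$class, cat_prof$rbp_n, sep = "=", collapse = ", "),
        " (one-tailed Fisher, uncorrected)")

pathways <- split(rep(catalog$protein, lengths(split_set(catalog$pathways))),
                  unlist(split_set(catalog$pathways)))
pw <- pathway_rbp_fraction(pathways, hit_sets)
write.table(pw, "results/enrichment/pathway_rbp_fraction.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- pw[order(-pw$fraction), ][1:5, ]
message("highest pathway RBP fractions: ",
        paste(sprintf("%s/%s %.2f", top$pathway, top$organ, top$fraction),
              collapse = ", "))
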