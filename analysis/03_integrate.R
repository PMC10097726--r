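#!/usr/bin/env Rscript
# Integrate per-organ poly(A) and non-poly(A) differential tables into the
# organ binding atlas: biotype classes (dual / exclusive / unresolved),
# cross-organ Venn counts, novel RBPs against the published-atlas flag,
# cell-line presence of the novel set, and the missing-in-organ cascade.

library(ricproteo)

organs <- c("brain", "kidney", "liver")
read_tab <- function(assay, org)
  read_differential_table(sprintf("results/differential/%s_%s.tsv", assay, org))
polya <- setNames(lapply(organs, read_tab, assay = "eric"), organs)
nonpolya <- setNames(lapply(organs, read_tab, assay = "nonpolya_ric"), organs)
catalog <- read_annotation_table("results/simulated/annotations.tsv")
dir.create("results/atlas", showWarnings = FALSE, recursive = TRUE)

atlas <- build_binding_atlas(polya, nonpolya, mode = "hit_only")
write_atlas_table(atlas, "results/atlas/binding_atlas.tsv")
message("biotype classes: ",
        paste(names(table(atlas$biotype_class)), table(atlas$biotype_class),
              sep = "=", collapse = ", "))

hit_sets <- atlas_hit_sets(atlas)
overlap <- cross_organ_overlap(hit_sets)
write.table(overlap, "results/atlas/organ_overlap.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

novel <- identify_novel_rbps(hit_sets, catalog)
message(length(novel$novel), " hits are absent from the published-atlas flag")
if (!is.null(novel$by_region))
  write.table(novel$by_region, "results/atlas/novel_by_region.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
profile <- cell_line_presence_profile(novel$novel, catalog, k_max = 10)
write.table(profile, "results/atlas/novel_cell_line_presence.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%d of %d novel RBPs are detected in >= 1 cell line (%.0f%%)",
                profile$count[1], length(novel$novel),
                100 * profile$count[1] / max(length(novel$novel), 1)))

# cell-line RBPs never captured in any organ assay
common <- common_cell_line_rbps(catalog)
inputs <- setNames(lapply(organs, function(o)
  catalog$protein[vapply(split_set(catalog$input_organs),
                         function(v) o %in% v, logical(1))]), organs)
cascade <- missing_in_organ_cascade(common, hit_sets,
                                    atlas_hit_sets(atlas, side = "nonpolya"),
                                    inputs)
sizes <- data.frame(stage = names(cascade), n = lengths(cascade))
write.table(sizes, "results/atlas/missing_rbp_cascade.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("cascade sizes: ", paste(sizes$stage, sizes$n, sep = "=",
                                 collapse = ", "))
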