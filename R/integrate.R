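# Integration of per-organ poly(A) and non-poly(A) differential tables into
# biotype classes and cross-organ set algebra. A protein scores "no_hit" when
# it is detected but not enriched over the non-crosslinked control;
# "not_detected" when absent from the assay's quantified protein list.

#' Classify the RNA-biotype binding class of a protein
#'
#' `dual` when both assays qualify; `exclusive_polya` when poly(A) qualifies
#' and the protein is not detected at all in the non-poly(A) assay;
#' `polya_unresolved` when poly(A) qualifies but the protein is detected yet
#' unenriched in the non-poly(A) assay (its non-poly(A) status cannot be
#' ruled either way); symmetric rules on the other side; `none` otherwise.
#'
#' @param polya,nonpolya enrichment classes (`hit`, `candidate`, `no_hit`,
#'   `not_detected`); vectorized.
#' @param mode `hit_only` (only hits qualify) or `hit_or_candidate`. The
#'   presets `fig4f` (hit-only) and `liver_deep` (hit-or-candidate) name the
#'   two analysis variants.
#' @return character vector of biotype classes.
#' @export
classify_biotype <- function(polya, nonpolya,
                             mode = c("hit_only", "hit_or_candidate",
                                      "fig4f", "liver_deep")) {
  mode <- match.arg(mode)
  qualifying <- if (mode %in% c("hit_only", "fig4f")) "hit"
                else c("hit", "candidate")
  polya <- as.character(polya)
  nonpolya <- as.character(nonpolya)
  bad <- setdiff(unique(c(polya, nonpolya)), ENRICH_CLASSES)
  if (length(bad) > 0L)
    stop("unknown enrichment class: ", paste(bad, collapse = ", "))
  pq <- polya %in% qualifying
  nq <- nonpolya %in% qualifying
  out <- rep("none", length(polya))
  out[pq & nq] <- "dual"
  out[pq & !nq] <- ifelse(nonpolya[pq & !nq] == "not_detected",
                          "exclusive_polya", "polya_unresolved")
  out[nq & !pq] <- ifelse(polya[nq & !pq] == "not_detected",
                          "exclusive_nonpolya", "nonpolya_unresolved")
  out
}

#' Build a binding atlas from per-organ differential tables
#'
#' @param polya_tables named list (organ -> differential table) for the
#'   poly(A) capture.
#' @param nonpolya_tables named list (organ -> differential table) for the
#'   non-poly(A) capture; organs missing from this list count as
#'   `not_detected`.
#' @param mode see [classify_biotype()].
#' @param extra_nonpolya_detected optional character vector (or per-organ
#'   named list) of proteins detected in an additional in-depth non-poly(A)
#'   run: such proteins can no longer be exclusive poly(A) binders (they are
#'   reclassified `polya_unresolved`).
#' @return an atlas data.frame (see [validate_atlas_table()]), one row per
#'   (protein, organ) for every protein observed in any assay of that organ.
#' @export
build_binding_atlas <- function(polya_tables, nonpolya_tables = list(),
                                mode = "hit_only",
                                extra_nonpolya_detected = NULL) {
  organs <- union(names(polya_tables), names(nonpolya_tables))
  rows <- lapply(organs, function(org) {
    pt <- polya_tables[[org]]
    nt <- nonpolya_tables[[org]]
    proteins <- union(if (is.null(pt)) character(0) else pt$protein,
                      if (is.null(nt)) character(0) else nt$protein)
    cls <- function(tab) {
      out <- rep("not_detected", length(proteins))
      if (!is.null(tab)) {
        m <- match(proteins, tab$protein)
        out[!is.na(m)] <- tab$enrich_class[m[!is.na(m)]]
      }
      out
    }
    polya_class <- cls(pt)
    nonpolya_class <- cls(nt)
    extra <- if (is.list(extra_nonpolya_detected))
      extra_nonpolya_detected[[org]] else extra_nonpolya_detected
    if (!is.null(extra)) {
      flip <- nonpolya_class == "not_detected" & proteins %in% extra
      nonpolya_class[flip] <- "no_hit"
    }
    data.frame(protein = proteins, organ = org, polya_class = polya_class,
               nonpolya_class = nonpolya_class,
               biotype_class = classify_biotype(polya_class, nonpolya_class,
                                                mode),
               stringsAsFactors = FALSE)
  })
  validate_atlas_table(do.call(rbind, rows))
}

#' Per-organ qualifying protein sets from an atlas
#'
#' @param atlas atlas data.frame.
#' @param class_filter which poly(A) classes qualify (default: hits).
#' @param side which assay's class column to use.
#' @return named list organ -> character vector of proteins.
#' @export
atlas_hit_sets <- function(atlas, class_filter = "hit",
                           side = c("polya", "nonpolya")) {
  side <- match.arg(side)
  col <- paste0(side, "_class")
  organs <- unique(atlas$organ)
  stats::setNames(lapply(organs, function(org)
    atlas$protein[atlas$organ == org & atlas[[col]] %in% class_filter]),
    organs)
}

#' Exact cross-organ overlap (Venn region) counts
#'
#' @param sets named list organ -> protein character vector, or an atlas
#'   data.frame (then `class_filter`/`side` select the qualifying sets).
#' @param organs organs to include (default: all; order fixes region labels).
#' @param class_filter,side forwarded to [atlas_hit_sets()] when `sets` is an
#'   atlas.
#' @return data.frame `region` (organ names joined by `&`, in input order),
#'   `n_organs`, `count`; every protein of the union is counted in exactly
#'   one region.
#' @export
cross_organ_overlap <- function(sets, organs = NULL, class_filter = "hit",
                                side = "polya") {
  if (is.data.frame(sets)) sets <- atlas_hit_sets(sets, class_filter, side)
  if (is.null(organs)) organs <- names(sets)
  unknown <- setdiff(organs, names(sets))
  if (length(unknown) > 0L)
    stop("unknown organ(s): ", paste(unknown, collapse = ", "))
  if (length(organs) < 2L) stop("need >= 2 organs")
  sets <- sets[organs]
  all_proteins <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) all_proteins %in% s,
                       logical(length(all_proteins)))
  if (length(all_proteins) == 1L) membership <- matrix(membership, nrow = 1)
  key <- apply(membership, 1, function(v) paste(organs[v], collapse = "&"))
  combos <- unlist(lapply(seq_along(organs), function(k)
    utils::combn(organs, k, paste, collapse = "&", simplify = FALSE)))
  counts <- table(factor(key, levels = combos))
  data.frame(region = names(counts),
             n_organs = lengths(strsplit(names(counts), "&", fixed = TRUE)),
             count = as.integer(counts), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Identify novel RBPs among organ hits
#'
#' Novel = organ hits absent from the published RBP-atlas membership flag in
#' the annotation catalog. Hits missing from the catalog are treated as
#' unknown (not novel) with a warning.
#'
#' @param hit_sets named list organ -> hit proteins (or an atlas data.frame).
#' @param catalog annotation catalog.
#' @return list: `novel` (character vector), `by_region` (data.frame region x
#'   novel count over the organ Venn of novel proteins).
#' @export
identify_novel_rbps <- function(hit_sets, catalog) {
  if (is.data.frame(hit_sets)) hit_sets <- atlas_hit_sets(hit_sets)
  catalog <- validate_annotation_catalog(catalog)
  all_hits <- unique(unlist(hit_sets, use.names = FALSE))
  m <- match(all_hits, catalog$protein)
  if (anyNA(m))
    warning(sum(is.na(m)), " hit(s) absent from the annotation catalog; ",
            "treated as known-status unknown (not novel)")
  novel <- all_hits[!is.na(m) & !catalog$known_rbp[m]]
  novel_sets <- lapply(hit_sets, function(s) intersect(s, novel))
  by_region <- if (length(hit_sets) >= 2L && length(novel) > 0L)
    cross_organ_overlap(novel_sets) else NULL
  list(novel = novel, by_region = by_region)
}

#' Cumulative cell-line presence histogram
#'
#' For k = 1..K, the number of proteins in `protein_set` detected in at least
#' k cell lines according to the catalog.
#'
#' @param protein_set character vector.
#' @param catalog annotation catalog with `cell_lines_detected`.
#' @param k_max largest k (default: the largest set size observed).
#' @return data.frame `k`, `count` (non-increasing in k).
#' @export
cell_line_presence_profile <- function(protein_set, catalog, k_max = NULL) {
  catalog <- validate_annotation_catalog(catalog)
  m <- match(protein_set, catalog$protein)
  n_lines <- lengths(split_set(catalog$cell_lines_detected[m]))
  n_lines[is.na(m)] <- 0L
  if (is.null(k_max)) k_max <- max(c(n_lines, 1L))
  data.frame(k = seq_len(k_max),
             count = vapply(seq_len(k_max), function(k) sum(n_lines >= k),
                            integer(1)))
}

#' Staged cascade of cell-line RBPs missing from the organ atlases
#'
#' Stage 1: RBPs commonly identified in cultured cells that are absent from
#' every organ poly(A) hit set. Stage 2: remove those detected in any
#' non-poly(A) hit set. Stage 3: split the remainder by detection in the
#' total-proteome inputs - proteins undetected in every input are excluded as
#' insufficiently expressed; proteins detected in *all* organs' inputs form
#' the final focus set (expressed everywhere yet never captured on RNA);
#' proteins detected in only some inputs are reported separately.
#'
#' @param common_rbps character vector of commonly identified cell-line RBPs
#'   (e.g. members of >= 50% of published atlas studies).
#' @param polya_hit_sets,nonpolya_hit_sets named lists organ -> protein sets.
#' @param input_detected named list organ -> proteins detected in that
#'   organ's total-proteome input.
#' @return list of character vectors: `stage1_absent_polya`,
#'   `detected_nonpolya`, `stage2_remaining`, `undetected_in_inputs`,
#'   `partially_detected`, `final_focus`.
#' @export
missing_in_organ_cascade <- function(common_rbps, polya_hit_sets,
                                     nonpolya_hit_sets, input_detected) {
  polya_all <- unique(unlist(polya_hit_sets, use.names = FALSE))
  nonpolya_all <- unique(unlist(nonpolya_hit_sets, use.names = FALSE))
  stage1 <- setdiff(common_rbps, polya_all)
  detected_np <- intersect(stage1, nonpolya_all)
  stage2 <- setdiff(stage1, nonpolya_all)
  in_all_inputs <- Reduce(intersect, input_detected)
  in_any_input <- unique(unlist(input_detected, use.names = FALSE))
  undetected <- setdiff(stage2, in_any_input)
  final <- intersect(stage2, in_all_inputs)
  partial <- setdiff(setdiff(stage2, undetected), final)
  list(stage1_absent_polya = stage1, detected_nonpolya = detected_np,
       stage2_remaining = stage2, undetected_in_inputs = undetected,
       partially_detected = partial, final_focus = final)
}

#' Select commonly identified cell-line RBPs from a catalog
#'
#' @param catalog annotation catalog with `atlas_report_fraction` (fraction
#'   of published atlas studies reporting the protein).
#' @param min_fraction membership threshold (default 0.5).
#' @return character vector of proteins.
#' @export
common_cell_line_rbps <- function(catalog, min_fraction = 0.5) {
  catalog <- validate_annotation_catalog(catalog)
  catalog$protein[!is.na(catalog$atlas_report_fraction) &
                    catalog$atlas_report_fraction >= min_fraction]
}
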