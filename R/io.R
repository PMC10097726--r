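# All tables are tab-separated, '.' decimal point regardless of locale,
# missing values encoded as empty cells. Schemas are versioned via a
# '# ricproteo-table <type> v1' comment in the first line.

SCHEMA_VERSIONS <- c(quant = "v1", sample_sheet = "v1", differential = "v1",
                     atlas = "v1", fraction = "v1", annotation = "v1",
                     rna_content = "v1")

.write_tsv <- function(df, path, type) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# ricproteo-table %s %s", type, SCHEMA_VERSIONS[[type]]),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", dec = ".")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    na.strings = "", check.names = FALSE,
                    stringsAsFactors = FALSE, dec = ".", quote = "")
}

RESERVED_QUANT_COLS <- c("protein", "unique_peptides", "predicted_mass_kda")

#' Read a protein quantification table with its sample sheet
#'
#' The quant table has one row per protein: a `protein` accession column,
#' a `unique_peptides` count, an optional `predicted_mass_kda` column, and
#' one intensity column per sample. Every intensity column must be declared
#' in the sample sheet and vice versa. Empty cells become explicit missing
#' values; zeros are kept as observed zeros.
#'
#' @param path path to the quant TSV.
#' @param sample_sheet path to the sample-sheet TSV, or a data.frame.
#' @return a [quant_matrix()].
#' @export
read_quant_table <- function(path, sample_sheet) {
  df <- .read_tsv(path)
  if (is.character(sample_sheet)) sample_sheet <- .read_tsv(sample_sheet)
  samples <- validate_sample_sheet(sample_sheet)
  if (!"protein" %in% names(df))
    stop("quant table is missing required column: protein")
  if (!"unique_peptides" %in% names(df))
    stop("quant table is missing required column: unique_peptides")
  intensity_cols <- setdiff(names(df), RESERVED_QUANT_COLS)
  extra <- setdiff(intensity_cols, samples$sample_id)
  if (length(extra) > 0L)
    stop("intensity column(s) not declared in sample sheet: ",
         paste(extra, collapse = ", "))
  absent <- setdiff(samples$sample_id, intensity_cols)
  if (length(absent) > 0L)
    stop("sample sheet sample_id(s) without an intensity column: ",
         paste(absent, collapse = ", "))
  intensity <- as.matrix(df[, samples$sample_id, drop = FALSE])
  rownames(intensity) <- as.character(df$protein)
  quant_matrix(intensity, samples, df$unique_peptides,
               predicted_mass_kda = df$predicted_mass_kda)
}

#' Write a quant_matrix (and optionally its sample sheet) to TSV
#'
#' @param q a [quant_matrix()].
#' @param path output path for the quant table.
#' @param sample_sheet_path optional output path for the sample sheet.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(q, path, sample_sheet_path = NULL) {
  stopifnot(inherits(q, "quant_matrix"))
  df <- data.frame(protein = rownames(q$intensity),
                   unique_peptides = unname(q$unique_peptides),
                   stringsAsFactors = FALSE)
  if (!is.null(q$predicted_mass_kda))
    df$predicted_mass_kda <- unname(q$predicted_mass_kda)
  df <- cbind(df, as.data.frame(q$intensity, check.names = FALSE))
  .write_tsv(df, path, "quant")
  if (!is.null(sample_sheet_path)) write_sample_sheet(q$samples, sample_sheet_path)
  invisible(path)
}

#' @rdname write_quant_table
#' @param samples a sample sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  .write_tsv(validate_sample_sheet(samples), path, "sample_sheet")
}

#' Read/write a differential enrichment table
#'
#' Columns: `protein`, `log2fc`, `t_mod`, `p_value`, `fdr`, `enrich_class`,
#' `n_unique_peptides` (plus any extra columns, preserved verbatim).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_differential_table <- function(path) {
  df <- .read_tsv(path)
  validate_differential_table(df)
}

#' @rdname read_differential_table
#' @param table a differential table data.frame.
#' @export
write_differential_table <- function(table, path) {
  .write_tsv(validate_differential_table(table), path, "differential")
}

#' @rdname read_differential_table
#' @export
validate_differential_table <- function(table) {
  req <- c("protein", "log2fc", "t_mod", "p_value", "fdr", "enrich_class",
           "n_unique_peptides")
  missing <- setdiff(req, names(table))
  if (length(missing) > 0L)
    stop("differential table missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(table$protein)) stop("duplicate protein in differential table")
  bad <- setdiff(unique(table$enrich_class), ENRICH_CLASSES)
  if (length(bad) > 0L) stop("unknown enrich_class: ", paste(bad, collapse = ", "))
  ok <- is.na(table$fdr) | (table$fdr >= 0 & table$fdr <= 1)
  if (!all(ok)) stop("fdr outside [0, 1]")
  ok <- is.na(table$p_value) | (table$p_value >= 0 & table$p_value <= 1)
  if (!all(ok)) stop("p_value outside [0, 1]")
  table$protein <- as.character(table$protein)
  table
}

#' Read/write a binding atlas table
#'
#' One row per (protein, organ) with the poly(A) class, the non-poly(A) class
#' and the derived biotype class.
#'
#' @param path file path.
#' @return data.frame with columns `protein`, `organ`, `polya_class`,
#'   `nonpolya_class`, `biotype_class`.
#' @export
read_atlas_table <- function(path) validate_atlas_table(.read_tsv(path))

#' @rdname read_atlas_table
#' @param atlas an atlas data.frame.
#' @export
write_atlas_table <- function(atlas, path) {
  .write_tsv(validate_atlas_table(atlas), path, "atlas")
}

#' @rdname read_atlas_table
#' @export
validate_atlas_table <- function(atlas) {
  req <- c("protein", "organ", "polya_class", "nonpolya_class", "biotype_class")
  missing <- setdiff(req, names(atlas))
  if (length(missing) > 0L)
    stop("atlas table missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("polya_class", "nonpolya_class")) {
    bad <- setdiff(unique(atlas[[col]]), ENRICH_CLASSES)
    if (length(bad) > 0L) stop("unknown ", col, ": ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(unique(atlas$biotype_class), BIOTYPE_CLASSES)
  if (length(bad) > 0L)
    stop("unknown biotype_class: ", paste(bad, collapse = ", "))
  if (anyDuplicated(atlas[, c("protein", "organ")]))
    stop("duplicate (protein, organ) in atlas table")
  atlas$protein <- as.character(atlas$protein)
  atlas$organ <- as.character(atlas$organ)
  atlas
}

#' Read/write a gel-fraction profile
#'
#' Long TSV with one row per (protein, replicate, fraction) cell: columns
#' `protein`, `predicted_mass_kda`, `replicate`, `fraction_index`,
#' `fraction_upper_kda`, `ibaq`, `valid` and optionally `peptides`.
#'
#' @param path file path.
#' @return a [fraction_profile()].
#' @export
read_fraction_table <- function(path) {
  df <- .read_tsv(path)
  req <- c("protein", "predicted_mass_kda", "replicate", "fraction_index",
           "fraction_upper_kda", "ibaq", "valid")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L)
    stop("fraction table missing column(s): ", paste(missing, collapse = ", "))
  proteins <- unique(df$protein)
  reps <- sort(unique(df$replicate))
  fr <- sort(unique(df$fraction_index))
  bounds <- df$fraction_upper_kda[match(fr, df$fraction_index)]
  dims <- c(length(proteins), length(reps), length(fr))
  ibaq <- array(NA_real_, dims, dimnames = list(proteins, reps, NULL))
  valid <- array(FALSE, dims, dimnames = dimnames(ibaq))
  peptides <- if ("peptides" %in% names(df))
    array(NA_integer_, dims, dimnames = dimnames(ibaq)) else NULL
  idx <- cbind(match(df$protein, proteins), match(df$replicate, reps),
               match(df$fraction_index, fr))
  ibaq[idx] <- df$ibaq
  valid[idx] <- as.logical(df$valid)
  if (!is.null(peptides)) peptides[idx] <- as.integer(df$peptides)
  mass <- df$predicted_mass_kda[match(proteins, df$protein)]
  fraction_profile(ibaq, mass, bounds_kda = bounds, valid = valid,
                   peptides = peptides)
}

#' @rdname read_fraction_table
#' @param fp a [fraction_profile()].
#' @export
write_fraction_table <- function(fp, path) {
  stopifnot(inherits(fp, "fraction_profile"))
  d <- dim(fp$ibaq)
  proteins <- dimnames(fp$ibaq)[[1]]
  reps <- dimnames(fp$ibaq)[[2]]
  if (is.null(reps)) reps <- as.character(seq_len(d[2]))
  grid <- expand.grid(p = seq_len(d[1]), r = seq_len(d[2]), f = seq_len(d[3]))
  df <- data.frame(protein = proteins[grid$p],
                   predicted_mass_kda = unname(fp$predicted_mass_kda[grid$p]),
                   replicate = reps[grid$r],
                   fraction_index = grid$f,
                   fraction_upper_kda = fp$bounds_kda[grid$f],
                   ibaq = fp$ibaq[as.matrix(grid)],
                   valid = fp$valid[as.matrix(grid)],
                   stringsAsFactors = FALSE)
  if (!is.null(fp$peptides)) df$peptides <- fp$peptides[as.matrix(grid)]
  .write_tsv(df, path, "fraction")
}

#' Read/write an annotation catalog
#' @param path file path.
#' @return data.frame (see [validate_annotation_catalog()]).
#' @export
read_annotation_table <- function(path) {
  validate_annotation_catalog(.read_tsv(path))
}

#' @rdname read_annotation_table
#' @param catalog annotation catalog data.frame.
#' @export
write_annotation_table <- function(catalog, path) {
  .write_tsv(validate_annotation_catalog(catalog), path, "annotation")
}

#' Read/write a per-tissue RNA-content table
#' @param path file path.
#' @return data.frame (see [validate_rna_content()]).
#' @export
read_rna_content <- function(path) validate_rna_content(.read_tsv(path))

#' @rdname read_rna_content
#' @param rna RNA-content data.frame.
#' @export
write_rna_content <- function(rna, path) {
  .write_tsv(validate_rna_content(rna), path, "rna_content")
}
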