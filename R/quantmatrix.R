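ENRICH_CLASSES <- c("hit", "candidate", "no_hit", "not_detected")
BIOTYPE_CLASSES <- c("dual", "exclusive_polya", "exclusive_nonpolya",
                     "polya_unresolved", "nonpolya_unresolved", "none")
ASSAYS <- c("eric", "nonpolya_ric", "input", "fraction")
CONDITIONS <- c("plusUV", "minusUV")

#' Validate a sample sheet
#'
#' A sample sheet describes one sample per row: reporter channel or LC-MS run
#' identity (`sample_id`), the organ it came from (`tissue`), the capture
#' protocol (`assay`: `eric` for poly(A) capture, `nonpolya_ric` for the
#' silica-based capture of the poly(A)-depleted supernatant, `input` for the
#' total proteome, `fraction` for gel fractions), the UV irradiation status
#' (`condition`), a replicate label and a batch label (typically the TMT run).
#'
#' @param samples data.frame with columns `sample_id`, `tissue`, `assay`,
#'   `condition`, `replicate`, `batch` and optionally `channel`.
#' @return the sample sheet, columns coerced to character (replicate kept
#'   as-is), invisibly usable downstream.
#' @export
validate_sample_sheet <- function(samples) {
  required <- c("sample_id", "tissue", "assay", "condition", "replicate", "batch")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0L)
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  bad <- setdiff(unique(as.character(samples$assay)), ASSAYS)
  if (length(bad) > 0L)
    stop("unknown assay value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(as.character(samples$condition)), CONDITIONS)
  if (length(bad) > 0L)
    stop("unknown condition value(s): ", paste(bad, collapse = ", "))
  for (col in c("tissue", "assay", "condition", "batch"))
    samples[[col]] <- as.character(samples[[col]])
  samples
}

#' Construct a protein x sample quantification matrix
#'
#' The central container of the pipeline: raw reporter-ion signal sums (or
#' iBAQ values) per protein and sample, together with sample metadata,
#' unique-peptide counts and, optionally, the predicted monomeric mass.
#' Missing values are explicit `NA`s; zeros are treated as observed values.
#'
#' @param intensity numeric matrix, proteins in rows (rownames = accessions),
#'   samples in columns (colnames = sample_id). Non-negative or `NA`.
#' @param samples sample sheet (see [validate_sample_sheet()]); row order must
#'   match the intensity columns by `sample_id`.
#' @param unique_peptides integer vector, one count per protein.
#' @param predicted_mass_kda optional numeric vector of predicted monomeric
#'   masses in kDa (positive or `NA`).
#' @return an object of class `quant_matrix`.
#' @export
quant_matrix <- function(intensity, samples, unique_peptides,
                         predicted_mass_kda = NULL) {
  samples <- validate_sample_sheet(samples)
  if (!is.matrix(intensity)) intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (is.null(rownames(intensity)))
    stop("intensity matrix must have protein accessions as rownames")
  if (is.null(colnames(intensity)))
    stop("intensity matrix must have sample_ids as colnames")
  if (anyDuplicated(rownames(intensity)))
    stop("duplicate protein accession(s): ",
         paste(unique(rownames(intensity)[duplicated(rownames(intensity))]),
               collapse = ", "))
  if (!setequal(colnames(intensity), samples$sample_id) ||
      ncol(intensity) != nrow(samples))
    stop("intensity columns and sample sheet sample_ids do not match")
  samples <- samples[match(colnames(intensity), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (any(intensity < 0, na.rm = TRUE))
    stop("negative intensity values are not allowed")
  unique_peptides <- as.integer(unique_peptides)
  if (length(unique_peptides) != nrow(intensity))
    stop("unique_peptides must have one entry per protein")
  if (any(is.na(unique_peptides)) || any(unique_peptides < 0L))
    stop("unique_peptides must be non-negative integers")
  if (!is.null(predicted_mass_kda)) {
    predicted_mass_kda <- as.numeric(predicted_mass_kda)
    if (length(predicted_mass_kda) != nrow(intensity))
      stop("predicted_mass_kda must have one entry per protein")
    if (any(predicted_mass_kda <= 0, na.rm = TRUE))
      stop("predicted_mass_kda must be positive where present")
  }
  structure(
    list(intensity = intensity, samples = samples,
         unique_peptides = stats::setNames(unique_peptides, rownames(intensity)),
         predicted_mass_kda = if (is.null(predicted_mass_kda)) NULL else
           stats::setNames(predicted_mass_kda, rownames(intensity))),
    class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d proteins x %d samples\n",
              nrow(x$intensity), ncol(x$intensity)))
  cat(sprintf("  tissues: %s\n", paste(unique(x$samples$tissue), collapse = ", ")))
  cat(sprintf("  assays:  %s\n", paste(unique(x$samples$assay), collapse = ", ")))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$intensity)

#' Subset a quant_matrix by proteins and/or samples
#'
#' @param q a `quant_matrix`.
#' @param proteins character or logical/integer index of proteins to keep.
#' @param sample_ids character or logical/integer index of samples to keep.
#' @return the subsetted `quant_matrix`.
#' @export
subset_quant <- function(q, proteins = NULL, sample_ids = NULL) {
  stopifnot(inherits(q, "quant_matrix"))
  ri <- if (is.null(proteins)) seq_len(nrow(q$intensity)) else proteins
  ci <- if (is.null(sample_ids)) seq_len(ncol(q$intensity)) else sample_ids
  intensity <- q$intensity[ri, ci, drop = FALSE]
  quant_matrix(intensity,
               q$samples[match(colnames(intensity), q$samples$sample_id), ,
                         drop = FALSE],
               q$unique_peptides[rownames(intensity)],
               if (is.null(q$predicted_mass_kda)) NULL else
                 q$predicted_mass_kda[rownames(intensity)])
}

#' Hit/candidate calling thresholds
#'
#' Defaults follow the enrichment definitions used throughout the analysis:
#' a *hit* requires FDR < 0.05 and fold-change > 2; a *candidate* FDR < 0.2
#' and fold-change > 1.5; proteins must be quantified with at least two
#' unique peptides to be tested at all.
#'
#' @param hit_fdr,hit_fc,cand_fdr,cand_fc,min_unique_peptides see defaults.
#' @return a list of class `rp_thresholds`.
#' @export
rp_thresholds <- function(hit_fdr = 0.05, hit_fc = 2.0,
                          cand_fdr = 0.2, cand_fc = 1.5,
                          min_unique_peptides = 2L) {
  if (!(hit_fdr > 0 && hit_fdr <= cand_fdr && cand_fdr <= 1))
    stop("need 0 < hit_fdr <= cand_fdr <= 1")
  if (!(hit_fc >= cand_fc && cand_fc > 1))
    stop("need hit_fc >= cand_fc > 1")
  if (min_unique_peptides < 1L) stop("min_unique_peptides must be >= 1")
  structure(list(hit_fdr = hit_fdr, hit_fc = hit_fc, cand_fdr = cand_fdr,
                 cand_fc = cand_fc,
                 min_unique_peptides = as.integer(min_unique_peptides)),
            class = "rp_thresholds")
}

#' Gel-fraction profile container
#'
#' Holds per-protein iBAQ values across ordered gel fractions and replicates,
#' the fraction upper mass bounds, a cell validity mask, and the predicted
#' monomeric mass per protein. The default bounds correspond to gel cuts at
#' 20, 25, 37, 50, 75, 100 and 150 kDa plus the unbounded top-of-gel region.
#'
#' @param ibaq 3-d numeric array `[protein, replicate, fraction]`, >= 0.
#' @param predicted_mass_kda numeric vector per protein (kDa).
#' @param bounds_kda strictly increasing upper bounds, last may be `Inf`.
#' @param valid logical array, same shape as `ibaq`.
#' @param peptides optional integer array of unique-peptide counts per cell.
#' @return object of class `fraction_profile`.
#' @export
fraction_profile <- function(ibaq, predicted_mass_kda,
                             bounds_kda = default_fraction_bounds(),
                             valid = NULL, peptides = NULL) {
  stopifnot(is.array(ibaq), length(dim(ibaq)) == 3L)
  if (is.null(dimnames(ibaq)[[1]]))
    stop("ibaq array must carry protein accessions in dimnames[[1]]")
  if (any(diff(bounds_kda) <= 0)) stop("fraction bounds must be strictly increasing")
  if (dim(ibaq)[3] != length(bounds_kda))
    stop("number of fractions must equal length(bounds_kda)")
  if (is.null(valid)) valid <- !is.na(ibaq)
  stopifnot(identical(dim(valid), dim(ibaq)))
  if (any(ibaq[valid] < 0, na.rm = TRUE)) stop("iBAQ values must be >= 0 where valid")
  predicted_mass_kda <- as.numeric(predicted_mass_kda)
  if (length(predicted_mass_kda) != dim(ibaq)[1])
    stop("predicted_mass_kda must have one entry per protein")
  if (!is.null(peptides)) stopifnot(identical(dim(peptides), dim(ibaq)))
  structure(list(ibaq = ibaq, valid = valid, peptides = peptides,
                 predicted_mass_kda = stats::setNames(predicted_mass_kda,
                                                      dimnames(ibaq)[[1]]),
                 bounds_kda = bounds_kda),
            class = "fraction_profile")
}

#' Default gel-fraction upper mass bounds (kDa)
#' @return numeric vector `c(20, 25, 37, 50, 75, 100, 150, Inf)`.
#' @export
default_fraction_bounds <- function() c(20, 25, 37, 50, 75, 100, 150, Inf)

#' Validate an annotation catalog
#'
#' One row per protein with external annotations consumed by the integration
#' and enrichment stages. Set-valued columns (`pathways`, `domains`,
#' `cofactors`, `cell_lines_detected`, `input_organs`) are semicolon-joined
#' strings; empty string means empty set.
#'
#' @param catalog data.frame with at least `protein` and `known_rbp`.
#' @return the catalog with defaulted optional columns.
#' @export
validate_annotation_catalog <- function(catalog) {
  if (!all(c("protein", "known_rbp") %in% names(catalog)))
    stop("annotation catalog needs at least columns protein, known_rbp")
  if (anyDuplicated(catalog$protein))
    stop("duplicate protein in annotation catalog")
  catalog$protein <- as.character(catalog$protein)
  catalog$known_rbp <- as.logical(catalog$known_rbp)
  defaults <- list(has_rbd = FALSE, protein_class = NA_character_,
                   catalytic_type = NA_character_,
                   catalytic_subtype = NA_character_,
                   pathways = "", domains = "", cofactors = "",
                   cell_lines_detected = "", input_organs = "",
                   atlas_report_fraction = NA_real_)
  for (nm in names(defaults))
    if (is.null(catalog[[nm]])) catalog[[nm]] <- defaults[[nm]]
  for (nm in c("pathways", "domains", "cofactors", "cell_lines_detected",
               "input_organs")) {
    catalog[[nm]] <- as.character(catalog[[nm]])
    catalog[[nm]][is.na(catalog[[nm]])] <- ""
  }
  catalog
}

#' Split a semicolon-joined set column into a list of character vectors
#' @param x character vector of `;`-joined tokens.
#' @return list of character vectors (empty for empty strings).
#' @export
split_set <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

#' Join a list of character vectors into semicolon-joined strings
#' @param x list of character vectors.
#' @return character vector.
#' @export
join_set <- function(x) vapply(x, paste, character(1), collapse = ";")

#' Validate an RNA-content table
#'
#' Per-tissue RNA yields in micrograms of RNA per milligram of total protein,
#' split into the poly(A) and non-poly(A) biotypes.
#'
#' @param rna data.frame with columns `tissue`, `polya_ug_per_mg_protein`,
#'   `nonpolya_ug_per_mg_protein`.
#' @return the validated table.
#' @export
validate_rna_content <- function(rna) {
  req <- c("tissue", "polya_ug_per_mg_protein", "nonpolya_ug_per_mg_protein")
  missing <- setdiff(req, names(rna))
  if (length(missing) > 0L)
    stop("RNA-content table missing column(s): ", paste(missing, collapse = ", "))
  if (any(rna$polya_ug_per_mg_protein <= 0) ||
      any(rna$nonpolya_ug_per_mg_protein <= 0))
    stop("RNA contents must be strictly positive")
  if (anyDuplicated(rna$tissue)) stop("duplicate tissue in RNA-content table")
  rna$tissue <- as.character(rna$tissue)
  rna
}
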