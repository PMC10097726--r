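# Cross-organ activity summaries: RNA-content adjustment of capture signal,
# mean signal-sum ratios, relative abundance heatmap matrices, hierarchical
# clustering, replicate correlation, and binding-vs-abundance decoupling.

#' Adjust capture signal by per-tissue RNA content
#'
#' Divides each sample's linear-scale intensity by the RNA content of its
#' tissue: the poly(A) content for eRIC samples, the non-poly(A) content for
#' non-poly(A)RIC samples. Input samples are left unadjusted.
#'
#' @param mat linear-scale matrix, columns = samples.
#' @param samples sample sheet matching the columns.
#' @param rna RNA-content table (see [validate_rna_content()]).
#' @return adjusted matrix.
#' @export
rna_adjust_signal <- function(mat, samples, rna) {
  stopifnot(is.matrix(mat))
  samples <- validate_sample_sheet(samples)
  rna <- validate_rna_content(rna)
  stopifnot(nrow(samples) == ncol(mat))
  capture <- samples$assay %in% c("eric", "nonpolya_ric")
  need <- unique(samples$tissue[capture])
  missing <- setdiff(need, rna$tissue)
  if (length(missing) > 0L)
    stop("RNA content missing for tissue(s): ", paste(missing, collapse = ", "))
  m <- match(samples$tissue, rna$tissue)
  divisor <- ifelse(samples$assay == "eric", rna$polya_ug_per_mg_protein[m],
                    ifelse(samples$assay == "nonpolya_ric",
                           rna$nonpolya_ug_per_mg_protein[m], 1))
  sweep(mat, 2, divisor, "/")
}

#' Per-group mean signal and all pairwise ratios
#'
#' Arithmetic mean of the linear-scale signal over all (protein, sample)
#' cells of each group, for the proteins in `protein_set`.
#'
#' @param mat linear-scale matrix (proteins x samples).
#' @param protein_set proteins to average over (must be non-empty).
#' @param groups character/factor per column (e.g. tissue).
#' @return list: `means` (named numeric), `ratios` (matrix, `ratios[i, j] =
#'   means[i] / means[j]`).
#' @export
mean_signal_summary <- function(mat, protein_set, groups) {
  stopifnot(is.matrix(mat), length(groups) == ncol(mat))
  protein_set <- intersect(protein_set, rownames(mat))
  if (length(protein_set) == 0L) stop("empty protein set")
  sub <- mat[protein_set, , drop = FALSE]
  groups <- as.character(groups)
  means <- vapply(unique(groups), function(g)
    mean(sub[, groups == g, drop = FALSE], na.rm = TRUE), numeric(1))
  if (any(!is.finite(means))) stop("a group has no observed cells")
  ratios <- outer(means, means, "/")
  list(means = means, ratios = ratios)
}

#' Log2 ratios to the per-protein within-family average
#'
#' For each protein and each sample family (capture columns and input columns
#' treated separately), computes `log2(value / row mean within family)` with
#' the arithmetic row mean on the linear scale. Rows with any missing cell in
#' either family are dropped (count reported via `message()`).
#'
#' @param capture_mat,input_mat linear-scale matrices sharing row accessions.
#' @param protein_set optional restriction.
#' @return matrix with the capture columns followed by the input columns.
#' @export
relative_abundance_matrix <- function(capture_mat, input_mat,
                                      protein_set = NULL) {
  shared <- intersect(rownames(capture_mat), rownames(input_mat))
  if (!is.null(protein_set)) shared <- intersect(shared, protein_set)
  e <- capture_mat[shared, , drop = FALSE]
  i <- input_mat[shared, , drop = FALSE]
  complete <- rowSums(is.na(e)) == 0L & rowSums(is.na(i)) == 0L
  if (any(!complete))
    message(sum(!complete), " protein(s) dropped for missing cells")
  e <- e[complete, , drop = FALSE]
  i <- i[complete, , drop = FALSE]
  rel <- function(m) log2(m / rowMeans(m))
  cbind(rel(e), rel(i))
}

#' Hierarchical clustering of relative-abundance profiles
#'
#' Agglomerative clustering with average linkage on the distance
#' `1 - Pearson correlation` across columns. Deterministic for a given input;
#' leaves are ordered by the merge tree with protein accession as tie-break
#' in the distance computation order.
#'
#' @param mat complete (no missing cells) numeric matrix, proteins in rows.
#' @param k number of clusters to cut (optional).
#' @param h cut height (optional, used when `k` is missing).
#' @return list: `hclust` (the tree), `order` (row indices in leaf order),
#'   `labels` (cluster id per protein, if `k` or `h` given), `heatmap`
#'   (the matrix in leaf order).
#' @export
cluster_rbps <- function(mat, k = NULL, h = NULL) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2L) stop("need >= 2 proteins to cluster")
  if (anyNA(mat)) stop("clustering input must have no missing cells")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(t(mat)))
  hc <- stats::hclust(d, method = "average")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k)
            else if (!is.null(h)) stats::cutree(hc, h = h)
            else NULL
  list(hclust = hc, order = hc$order, labels = labels,
       heatmap = mat[hc$order, , drop = FALSE])
}

#' Pearson correlation between replicate sample pairs
#'
#' @param mat normalized (glog2) matrix.
#' @param pairs data.frame/matrix with two columns of sample ids (or a list
#'   of length-2 vectors).
#' @param min_overlap minimum number of pairwise-complete proteins.
#' @return data.frame `sample_1`, `sample_2`, `n_shared`, `r` (`NA` with a
#'   warning when the overlap is insufficient).
#' @export
replicate_correlation <- function(mat, pairs, min_overlap = 3L) {
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, lapply(pairs, function(p) data.frame(s1 = p[1],
                                                                 s2 = p[2])))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    s1 <- as.character(pairs[i, 1]); s2 <- as.character(pairs[i, 2])
    x <- mat[, s1]; y <- mat[, s2]
    ok <- !is.na(x) & !is.na(y)
    r <- if (sum(ok) >= min_overlap) stats::cor(x[ok], y[ok]) else {
      warning("pair (", s1, ", ", s2, ") has fewer than ", min_overlap,
              " shared observed proteins")
      NA_real_
    }
    data.frame(sample_1 = s1, sample_2 = s2, n_shared = sum(ok), r = r,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify binding-vs-abundance decoupling between two organs
#'
#' Compares a capture (eRIC) differential table between two organs with the
#' matching total-proteome (input) differential table, both computed under
#' equal-mean renormalization. `binding_only` proteins change RNA binding
#' with essentially unchanged abundance; `abundance_only` the reverse;
#' `concordant` both change in the same direction; `neither` otherwise.
#'
#' @param capture_tab,input_tab differential tables with `protein`, `log2fc`,
#'   `fdr` over the same organ pair contrast.
#' @param thresholds a [rp_thresholds()] (significance = hit thresholds,
#'   two-sided: `fdr < hit_fdr` and `|log2fc| >= log2(hit_fc)`).
#' @param abundance_tol log2 tolerance under which abundance (or binding) is
#'   considered unchanged.
#' @return data.frame `protein`, `capture_log2fc`, `input_log2fc`,
#'   `decoupling_class`.
#' @export
binding_vs_abundance <- function(capture_tab, input_tab,
                                 thresholds = rp_thresholds(),
                                 abundance_tol = log2(1.5)) {
  shared <- intersect(capture_tab$protein, input_tab$protein)
  ce <- capture_tab[match(shared, capture_tab$protein), ]
  ab <- input_tab[match(shared, input_tab$protein), ]
  sig <- function(tab) !is.na(tab$fdr) & tab$fdr < thresholds$hit_fdr &
    !is.na(tab$log2fc) & abs(tab$log2fc) >= log2(thresholds$hit_fc)
  flat <- function(tab) !is.na(tab$log2fc) & abs(tab$log2fc) < abundance_tol
  cls <- rep("neither", length(shared))
  cls[sig(ce) & flat(ab)] <- "binding_only"
  cls[sig(ab) & flat(ce)] <- "abundance_only"
  conc <- sig(ce) & sig(ab) & sign(ce$log2fc) == sign(ab$log2fc)
  cls[conc] <- "concordant"
  data.frame(protein = shared, capture_log2fc = ce$log2fc,
             input_log2fc = ab$log2fc, decoupling_class = cls,
             stringsAsFactors = FALSE)
}
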