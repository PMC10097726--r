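# Fisher-exact overrepresentation of annotation terms (domains, protein
# classes, pathways, catalytic types, cofactors) with Benjamini-Hochberg
# correction across terms.

#' Fisher-exact term enrichment of a foreground against a contrast set
#'
#' Builds per term the 2x2 table (foreground with term, foreground without,
#' contrast with, contrast without). By default the contrast is
#' `background \ foreground`; with `disjoint_contrast = TRUE` the background
#' set is used as-is (caller guarantees disjointness). One-tailed p-values
#' are the exact hypergeometric upper tail; two-sided p-values use the
#' point-probability (minimum-likelihood) rule. The sample odds ratio
#' `(a d)/(b c)` gets a Haldane 0.5 continuity correction when any cell is
#' zero. Terms never seen with the term (`a + c = 0`) are skipped.
#'
#' @param foreground protein character vector (non-empty).
#' @param background protein character vector (superset of the foreground
#'   unless `disjoint_contrast`).
#' @param annotation named list term -> protein character vector, or a
#'   data.frame with columns `protein`, `term`.
#' @param tail `"greater"` (one-tailed overrepresentation) or `"two_sided"`.
#' @param disjoint_contrast treat `background` as an already-disjoint
#'   contrast set.
#' @return data.frame per term: `term`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_value`, `fdr` (BH across the tested terms).
#' @export
fisher_enrichment <- function(foreground, background, annotation,
                              tail = c("greater", "two_sided"),
                              disjoint_contrast = FALSE) {
  tail <- match.arg(tail)
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  if (length(foreground) == 0L) stop("empty foreground")
  if (is.data.frame(annotation))
    annotation <- split(as.character(annotation$protein),
                        as.character(annotation$term))
  contrast <- if (disjoint_contrast) background
              else setdiff(background, foreground)
  if (!disjoint_contrast && length(setdiff(foreground, background)) > 0L)
    stop("foreground must be a subset of the background ",
         "(or use disjoint_contrast = TRUE)")
  rows <- lapply(names(annotation), function(term) {
    with_term <- annotation[[term]]
    a <- sum(foreground %in% with_term)
    c_ <- sum(contrast %in% with_term)
    if (a + c_ == 0L) return(NULL)
    b <- length(foreground) - a
    d <- length(contrast) - c_
    p <- if (tail == "greater")
      stats::phyper(a - 1L, a + c_, b + d, a + b, lower.tail = FALSE)
    else
      stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    or <- if (min(a, b, c_, d) == 0L)
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    else (a * d) / (b * c_)
    data.frame(term = term, a = a, b = b, c = c_, d = d, odds_ratio = or,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0),
                      odds_ratio = numeric(0), p_value = numeric(0),
                      fdr = numeric(0)))
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p_value)
  rownames(out) <- NULL
  out
}

#' Nucleotide-binding domain and cofactor enrichment among enzyme-RBPs
#'
#' Foreground: metabolite interconversion enzymes that are capture hits in at
#' least one organ. Contrast: enzymes detected in total-proteome inputs but
#' never in capture eluates. Per domain class (from the domain map) and per
#' cofactor (plus the pooled "any nucleotide" categories): proportions in
#' both groups, two-sided Fisher p, BH correction.
#'
#' @param hit_proteins capture hits (>= 1 organ), character vector.
#' @param eluate_detected proteins detected in any capture eluate.
#' @param input_detected proteins detected in any total-proteome input.
#' @param catalog annotation catalog (`protein_class`, `domains`, `cofactors`).
#' @param domain_map data.frame `domain`, `nucleotide_class` classifying
#'   domains as nucleotide-binding categories.
#' @param enzyme_class protein class defining "enzyme".
#' @return data.frame: `category`, `kind` (`domain`/`cofactor`), `fg_with`,
#'   `fg_total`, `fg_prop`, `bg_with`, `bg_total`, `bg_prop`, `odds_ratio`,
#'   `p_value`, `fdr`.
#' @export
cofactor_domain_enrichment <- function(hit_proteins, eluate_detected,
                                       input_detected, catalog,
                                       domain_map = simulated_domain_map(),
                                       enzyme_class =
                                         "metabolite interconversion enzyme") {
  catalog <- validate_annotation_catalog(catalog)
  no_class <- is.na(catalog$protein_class)
  if (any(no_class))
    message(sum(no_class), " protein(s) without class annotation excluded")
  enzymes <- catalog$protein[!no_class & catalog$protein_class == enzyme_class]
  fg <- intersect(enzymes, hit_proteins)
  bg <- intersect(enzymes, setdiff(input_detected, eluate_detected))
  if (length(fg) == 0L || length(bg) == 0L)
    stop("empty enzyme foreground or contrast set")

  doms <- split_set(catalog$domains)
  cofs <- split_set(catalog$cofactors)
  names(doms) <- names(cofs) <- catalog$protein
  nt_domains <- domain_map$domain
  nt_cofactors <- c("NAD(P)", "ATP", "AMP", "FAD", "CoA")

  categories <- list()
  for (cl in unique(domain_map$nucleotide_class)) {
    dset <- domain_map$domain[domain_map$nucleotide_class == cl]
    categories[[paste0("domain:", cl)]] <-
      names(doms)[vapply(doms, function(d) any(d %in% dset), logical(1))]
  }
  categories[["domain:any nucleotide"]] <-
    names(doms)[vapply(doms, function(d) any(d %in% nt_domains), logical(1))]
  all_cof <- unique(unlist(cofs, use.names = FALSE))
  for (cf in all_cof)
    categories[[paste0("cofactor:", cf)]] <-
      names(cofs)[vapply(cofs, function(d) cf %in% d, logical(1))]
  categories[["cofactor:any nucleotide"]] <-
    names(cofs)[vapply(cofs, function(d) any(d %in% nt_cofactors), logical(1))]

  res <- fisher_enrichment(fg, bg, categories, tail = "two_sided",
                           disjoint_contrast = TRUE)
  if (nrow(res) == 0L) return(res)
  kind <- sub(":.*$", "", res$term)
  data.frame(category = sub("^[^:]+:", "", res$term), kind = kind,
             fg_with = res$a, fg_total = res$a + res$b,
             fg_prop = res$a / (res$a + res$b),
             bg_with = res$c, bg_total = res$c + res$d,
             bg_prop = res$c / (res$c + res$d),
             odds_ratio = res$odds_ratio, p_value = res$p_value,
             fdr = res$fdr, stringsAsFactors = FALSE)
}

#' Catalytic type/subtype profile of enzyme-RBPs versus other enzymes
#'
#' Counts enzymes per catalytic type (and subtype) in the RBP and non-RBP
#' groups, with per-class one-tailed Fisher tests. P-values are deliberately
#' left uncorrected (flagged in the output).
#'
#' @param rbp_enzymes,other_enzymes protein character vectors.
#' @param catalog annotation catalog with `catalytic_type`,
#'   `catalytic_subtype`.
#' @param level `"type"` or `"subtype"`.
#' @return data.frame: `class`, `rbp_n`, `other_n`, `odds_ratio`, `p_value`,
#'   `corrected` (always `FALSE`).
#' @export
catalytic_class_profile <- function(rbp_enzymes, other_enzymes, catalog,
                                    level = c("type", "subtype")) {
  level <- match.arg(level)
  catalog <- validate_annotation_catalog(catalog)
  col <- paste0("catalytic_", level)
  cls <- stats::setNames(catalog[[col]], catalog$protein)
  g1 <- cls[intersect(rbp_enzymes, catalog$protein)]
  g2 <- cls[intersect(other_enzymes, catalog$protein)]
  g1 <- g1[!is.na(g1)]
  g2 <- g2[!is.na(g2)]
  classes <- sort(unique(c(g1, g2)))
  rows <- lapply(classes, function(k) {
    a <- sum(g1 == k); b <- length(g1) - a
    c_ <- sum(g2 == k); d <- length(g2) - c_
    p <- stats::phyper(a - 1L, a + c_, b + d, a + b, lower.tail = FALSE)
    or <- if (min(a, b, c_, d) == 0L)
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    else (a * d) / (b * c_)
    data.frame(class = k, rbp_n = a, other_n = c_, odds_ratio = or,
               p_value = p, corrected = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of pathway members identified as RBP hits per organ
#'
#' @param pathways named list pathway id -> member proteins.
#' @param hit_sets named list organ -> hit proteins.
#' @param input_detected optional named list organ -> proteins detected in
#'   that organ's input; when provided, the denominator is restricted to
#'   input-detected members (otherwise all members count).
#' @return data.frame: `pathway`, `organ`, `n_members`, `n_denominator`,
#'   `n_hits`, `fraction`.
#' @export
pathway_rbp_fraction <- function(pathways, hit_sets, input_detected = NULL) {
  stopifnot(length(pathways) > 0L)
  rows <- list()
  for (pw in names(pathways)) {
    members <- unique(pathways[[pw]])
    for (org in names(hit_sets)) {
      denom_set <- if (is.null(input_detected)) members
                   else intersect(members, input_detected[[org]])
      n_hit <- length(intersect(denom_set, hit_sets[[org]]))
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = pw, organ = org, n_members = length(members),
        n_denominator = length(denom_set), n_hits = n_hit,
        fraction = if (length(denom_set) == 0L) NA_real_
                   else n_hit / length(denom_set),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
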