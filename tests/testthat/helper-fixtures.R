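# Shared fixtures: tiny deterministic experiments built in code.

make_samples <- function(tissue = "liver", assay = "eric",
                         n_plus = 2L, n_minus = 1L, batch = NULL) {
  n <- n_plus + n_minus
  data.frame(
    sample_id = sprintf("%s_%s_s%d", tissue, assay, seq_len(n)),
    tissue = tissue, assay = assay,
    condition = rep(c("plusUV", "minusUV"), c(n_plus, n_minus)),
    replicate = c(seq_len(n_plus), seq_len(n_minus)),
    batch = if (is.null(batch)) "b1" else batch,
    stringsAsFactors = FALSE)
}

make_quant <- function(n_proteins = 5L, samples = make_samples(),
                       intensity = NULL, peptides = NULL, mass = NULL,
                       seed = 42L) {
  set.seed(seed)
  n <- nrow(samples)
  if (is.null(intensity))
    intensity <- matrix(round(2^rnorm(n_proteins * n, 20, 1), 3),
                        n_proteins, n)
  rownames(intensity) <- sprintf("P%03d", seq_len(n_proteins))
  colnames(intensity) <- samples$sample_id
  if (is.null(peptides)) peptides <- rep(3L, n_proteins)
  quant_matrix(intensity, samples, peptides, predicted_mass_kda = mass)
}

# brute-force BH step-up oracle, independent of stats::p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force one-tailed Fisher p: sum of hypergeometric point probabilities
# over all tables at least as extreme (a' >= a) with the same margins
fisher_oracle_greater <- function(a, b, c_, d) {
  m <- a + c_   # total with term
  n <- b + d    # total without
  k <- a + b    # foreground size
  amax <- min(m, k)
  sum(vapply(a:amax, function(ai)
    exp(lchoose(m, ai) + lchoose(n, k - ai) - lchoose(m + n, k)), numeric(1)))
}

# brute-force average-linkage agglomeration returning merge heights
average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i >= j) next
      h <- mean(d[active[[i]], active[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best]
    active[[length(active) + 1L]] <- merged
  }
  heights
}
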