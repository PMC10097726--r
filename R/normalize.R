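# Normalization: per-protein batch-effect removal on the log scale and an
# affine-arsinh variance-stabilizing transform calibrated per sample stratum
# by alternating trimmed least squares.

#' Remove additive batch effects from a log-scale matrix
#'
#' Fits, per protein, ordinary least squares of log intensity on the design
#' `[keep_design | batch indicators]` using the observed cells, and subtracts
#' only the fitted batch component. Terms in `keep_design` (e.g. condition,
#' tissue) are preserved.
#'
#' @param log_matrix numeric matrix on a log scale (proteins x samples),
#'   missing values allowed.
#' @param batch factor/character of batch labels, one per column.
#' @param keep_design numeric design matrix of terms to preserve (one row per
#'   column of `log_matrix`); defaults to an intercept.
#' @return corrected matrix, same shape and dimnames.
#' @export
remove_batch_effects <- function(log_matrix, batch,
                                 keep_design = matrix(1, ncol(log_matrix), 1)) {
  stopifnot(is.matrix(log_matrix))
  batch <- factor(batch)
  if (length(batch) != ncol(log_matrix))
    stop("batch must have one label per sample")
  if (nlevels(batch) == 1L) return(log_matrix)
  keep_design <- as.matrix(keep_design)
  # reference coding: the first batch level is the untouched reference and
  # every other batch is shifted onto it
  bmat <- stats::model.matrix(~batch)[, -1, drop = FALSE]
  colnames(bmat) <- paste0("batch", levels(batch)[-1])
  X <- cbind(keep_design, bmat)
  qr_full <- qr(X)
  if (qr_full$rank < ncol(X)) {
    dropped <- colnames(X)[qr_full$pivot[(qr_full$rank + 1L):ncol(X)]]
    stop("batch is confounded with preserved design terms; ",
         "rank-deficient column(s): ", paste(dropped, collapse = ", "))
  }
  nkeep <- ncol(keep_design)
  out <- log_matrix
  obs_pattern <- apply(!is.na(log_matrix), 1, function(v)
    paste(as.integer(v), collapse = ""))
  for (pat in unique(obs_pattern)) {
    rows <- which(obs_pattern == pat)
    cols <- which(strsplit(pat, "")[[1]] == "1")
    if (length(cols) == 0L) next
    Xo <- X[cols, , drop = FALSE]
    qro <- qr(Xo)
    if (qro$rank < ncol(Xo)) {
      # batch not estimable on these cells: leave the rows uncorrected
      next
    }
    Y <- t(log_matrix[rows, cols, drop = FALSE])
    beta <- qr.coef(qro, Y)
    batch_fit <- bmat[cols, , drop = FALSE] %*%
      beta[(nkeep + 1L):ncol(X), , drop = FALSE]
    out[rows, cols] <- log_matrix[rows, cols, drop = FALSE] - t(batch_fit)
  }
  out
}

#' Define VST strata and fitted samples for a normalization strategy
#'
#' Three strategies are supported. `per-tissue-condition` estimates
#' calibration coefficients separately for each (tissue, assay, condition)
#' group. `single-plusUV` pools all +UV capture samples of one assay across
#' tissues into a single stratum (-UV controls keep per-tissue-condition
#' strata). `plusUV-only` puts each (tissue, assay) in one stratum but fits
#' the coefficients on the +UV samples only, so the abundance difference from
#' the -UV control is maintained; the -UV samples are transformed with the
#' mean coefficients of their stratum.
#'
#' @param samples sample sheet.
#' @param strategy one of `"per-tissue-condition"`, `"single-plusUV"`,
#'   `"plusUV-only"`.
#' @return list with `strata` (character per sample) and `fit_on` (logical
#'   per sample).
#' @export
vst_strata <- function(samples,
                       strategy = c("per-tissue-condition", "single-plusUV",
                                    "plusUV-only")) {
  strategy <- match.arg(strategy)
  samples <- validate_sample_sheet(samples)
  plus <- samples$condition == "plusUV"
  strata <- switch(strategy,
    "per-tissue-condition" = paste(samples$tissue, samples$assay,
                                   samples$condition, sep = "."),
    "single-plusUV" = ifelse(plus, paste("plusUV", samples$assay, sep = "."),
                             paste(samples$tissue, samples$assay,
                                   samples$condition, sep = ".")),
    "plusUV-only" = paste(samples$tissue, samples$assay, sep = "."))
  fit_on <- if (strategy == "plusUV-only") plus else rep(TRUE, nrow(samples))
  list(strata = strata, fit_on = fit_on)
}

# Penalized trimmed least-squares objective for one sample's (a, b) against
# row targets mu on the glog2 scale; par = c(a, log b). The Jacobian term
# -sum(log h'(x)) (scaled by the current residual variance sigma2) removes
# the degenerate minima of the bare least-squares objective, where the
# transform collapses all columns by b -> 0 or |a| -> Inf; without it the
# alternating fit drifts instead of converging (the same device the
# maximum-likelihood calibration of glog transforms uses).
.vst_sample_obj <- function(par, x, mu, sigma2) {
  b <- exp(par[2])
  z <- par[1] + b * x
  h <- asinh(z) / log(2)
  sum((h - mu)^2) / (2 * sigma2) +
    sum(0.5 * log1p(z^2)) - length(x) * par[2]
}

.vst_sample_grad <- function(par, x, mu, sigma2) {
  b <- exp(par[2])
  z <- par[1] + b * x
  h <- asinh(z) / log(2)
  common <- (h - mu) / (sigma2 * log(2) * sqrt(1 + z^2))
  jac <- z / (1 + z^2)
  c(sum(common) + sum(jac),
    sum(common * b * x) + sum(jac * b * x) - length(x))
}

#' Affine-arsinh variance-stabilizing transform
#'
#' Transforms each sample as `h_s(x) = arsinh(a_s + b_s * x) / ln(2)` (the
#' glog2 scale: approximately `log2` at high intensity, linear near zero).
#' Calibration coefficients are estimated within each stratum by alternating
#' trimmed least squares: (i) compute protein row means over the stratum in
#' transformed space and keep the least-variable fraction (`trim`) of
#' proteins by residual sum of squares; (ii) refit each sample's `(a_s, b_s)`
#' to minimize the trimmed squared deviation from the row means. Iterate to
#' relative parameter change below `tol` or `max_iter` iterations.
#'
#' The fit is anchored by initializing `b_s = 1/median(x_s)`, `a_s = 0`, and
#' holding the within-stratum product of `b_s` at its initial value, which
#' removes the approximate scale gauge freedom of the objective and keeps
#' strata mutually location-comparable. A single-sample stratum is
#' scale-only: it keeps its anchored initial coefficients.
#'
#' @param q a [quant_matrix()], or a bare non-negative matrix.
#' @param strata character/factor per sample defining calibration strata
#'   (default: all samples in one stratum). See [vst_strata()].
#' @param fit_on optional logical (or sample_id character) subset of samples
#'   used for fitting; excluded samples are transformed with the mean
#'   coefficients of their stratum but do not influence the fit.
#' @param trim fraction of proteins kept in the trimmed fit.
#' @param tol relative parameter-change convergence tolerance.
#' @param max_iter maximum alternations.
#' @return list with `mat` (glog2-transformed matrix) and `params`
#'   (data.frame per sample: `sample_id`, `stratum`, `a`, `b`, `iterations`,
#'   `converged`, `final_rel_change`).
#' @export
variance_stabilizing_transform <- function(q, strata = NULL, fit_on = NULL,
                                           trim = 0.9, tol = 1e-8,
                                           max_iter = 50L) {
  x <- if (inherits(q, "quant_matrix")) q$intensity else as.matrix(q)
  if (any(x < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  S <- ncol(x)
  if (is.null(strata)) strata <- rep("all", S)
  strata <- as.character(strata)
  if (length(strata) != S) stop("strata must have one entry per sample")
  if (is.null(fit_on)) fit_on <- rep(TRUE, S)
  if (is.character(fit_on)) fit_on <- colnames(x) %in% fit_on
  if (is.numeric(fit_on)) fit_on <- seq_len(S) %in% fit_on
  stopifnot(is.logical(fit_on), length(fit_on) == S)
  all_missing <- colSums(!is.na(x)) == 0L
  if (any(all_missing))
    stop("sample(s) with no observed values: ",
         paste(colnames(x)[all_missing], collapse = ", "))

  a <- rep(0, S)
  b <- apply(x, 2, function(v) {
    m <- stats::median(v, na.rm = TRUE)
    if (!is.finite(m) || m <= 0) 1 else 1 / m
  })
  iter_info <- data.frame(sample_id = colnames(x), stratum = strata,
                          a = a, b = b, iterations = 0L, converged = TRUE,
                          final_rel_change = 0, stringsAsFactors = FALSE)

  for (st in unique(strata)) {
    cols <- which(strata == st)
    fit_cols <- cols[fit_on[cols]]
    if (length(fit_cols) == 0L)
      stop("stratum '", st, "' has no samples selected for fitting")
    if (length(fit_cols) >= 2L) {
      res <- .vst_fit_stratum(x[, fit_cols, drop = FALSE],
                              a[fit_cols], b[fit_cols],
                              trim = trim, tol = tol, max_iter = max_iter)
      a[fit_cols] <- res$a
      b[fit_cols] <- res$b
      iter_info$iterations[fit_cols] <- res$iterations
      iter_info$converged[fit_cols] <- res$converged
      iter_info$final_rel_change[fit_cols] <- res$final_rel_change
      if (!res$converged)
        warning("VST did not converge in stratum '", st,
                "' (relative change ", signif(res$final_rel_change, 3),
                "); best iterate returned")
    }
    # non-fitted samples take the mean coefficients of their stratum
    rest <- setdiff(cols, fit_cols)
    if (length(rest) > 0L) {
      a[rest] <- mean(a[fit_cols])
      b[rest] <- exp(mean(log(b[fit_cols])))
    }
  }
  iter_info$a <- a
  iter_info$b <- b
  mat <- asinh(sweep(sweep(x, 2, b, "*"), 2, a, "+")) / log(2)
  dimnames(mat) <- dimnames(x)
  list(mat = mat, params = iter_info)
}

.vst_fit_stratum <- function(x, a, b, trim, tol, max_iter) {
  n <- ncol(x)
  prod_b0 <- sum(log(b))
  rel_change <- Inf
  it <- 0L
  keep_frozen <- NULL
  while (it < max_iter && rel_change >= tol) {
    it <- it + 1L
    h <- asinh(sweep(sweep(x, 2, b, "*"), 2, a, "+")) / log(2)
    mu <- rowMeans(h, na.rm = TRUE)
    if (is.null(keep_frozen)) {
      resid_ss <- rowSums((h - mu)^2, na.rm = TRUE)
      n_obs <- rowSums(!is.na(h))
      eligible <- which(n_obs >= 2L)
      if (length(eligible) < 3L)
        stop("too few proteins observed in >= 2 samples for VST fitting")
      keep_n <- max(3L, floor(trim * length(eligible)))
      keep <- eligible[order(resid_ss[eligible])][seq_len(keep_n)]
      # freeze the trimmed set once the parameters have settled (or past
      # half the budget) so re-selection cannot cycle indefinitely
      if (rel_change < 1e-3 || it > max_iter %/% 2L) keep_frozen <- keep
    } else {
      keep <- keep_frozen
    }
    resid_keep <- (h - mu)[keep, , drop = FALSE]
    sigma2 <- max(mean(resid_keep^2, na.rm = TRUE), 1e-12)
    a_new <- a
    b_new <- b
    for (j in seq_len(n)) {
      obs <- keep[!is.na(x[keep, j])]
      if (length(obs) < 2L) next
      opt <- stats::optim(c(a[j], log(b[j])), .vst_sample_obj,
                          gr = .vst_sample_grad,
                          x = x[obs, j], mu = mu[obs], sigma2 = sigma2,
                          method = "BFGS",
                          control = list(maxit = 100, reltol = 1e-12))
      a_new[j] <- opt$par[1]
      b_new[j] <- exp(opt$par[2])
    }
    denom <- pmax(abs(c(a, log(b))), 1)
    rel_change <- max(abs(c(a_new - a, log(b_new) - log(b))) / denom)
    a <- a_new
    b <- b_new
  }
  # anchor: restore the initial within-stratum product of b (a pure rescale
  # of the fitted transform) so different strata remain location-comparable
  # on the glog2 scale; within-stratum coefficient ratios are unchanged
  gamma <- exp((prod_b0 - sum(log(b))) / n)
  list(a = a * gamma, b = b * gamma, iterations = it,
       converged = rel_change < tol, final_rel_change = rel_change)
}

#' Renormalize samples to equal mean signal intensity
#'
#' Subtracts each listed sample's mean over the shared observed proteins and
#' adds back the grand mean, so that all listed columns have equal means over
#' the shared protein set. Used for the organ comparison that deliberately
#' discards overall capture-efficiency differences between samples.
#'
#' @param mat transformed (glog2) matrix.
#' @param sample_ids columns to adjust (default: all).
#' @return adjusted matrix.
#' @export
equal_mean_renormalization <- function(mat, sample_ids = colnames(mat)) {
  stopifnot(is.matrix(mat))
  cols <- if (is.character(sample_ids)) match(sample_ids, colnames(mat))
          else sample_ids
  if (anyNA(cols)) stop("unknown sample_id(s)")
  shared <- rowSums(is.na(mat[, cols, drop = FALSE])) == 0L
  if (!any(shared)) stop("no proteins observed in all listed samples")
  mns <- colMeans(mat[shared, cols, drop = FALSE])
  grand <- mean(mns)
  out <- mat
  out[, cols] <- sweep(mat[, cols, drop = FALSE], 2, mns - grand, "-")
  out
}
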