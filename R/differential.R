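# Per-protein linear modeling of +UV vs -UV enrichment with empirical-Bayes
# variance moderation. The design carries the UV condition and the replicate
# factor; the tested contrast is plusUV - minusUV. Single -UV replicate
# designs are supported (residual df can be 1); pooling the per-protein
# variances toward the empirical-Bayes prior is what makes testing in such
# small designs well-posed.

#' Remove proteins quantified with too few unique peptides
#'
#' @param q a [quant_matrix()].
#' @param min_unique minimum unique-peptide count (default 2).
#' @return the filtered [quant_matrix()]; the number of removed proteins is
#'   reported via `message()`.
#' @export
peptide_filter <- function(q, min_unique = 2L) {
  stopifnot(inherits(q, "quant_matrix"))
  keep <- q$unique_peptides >= min_unique
  if (!all(keep))
    message(sum(!keep), " protein(s) removed by the >=", min_unique,
            " unique-peptide filter (", sum(keep), " kept)")
  subset_quant(q, proteins = which(keep))
}

#' Build the enrichment design matrix (condition + replicate factor)
#'
#' @param samples sample sheet rows for the samples being modeled.
#' @return list with `design` (numeric matrix), `contrast` (numeric vector
#'   encoding plusUV - minusUV on the coefficients).
#' @export
make_design <- function(samples) {
  samples <- validate_sample_sheet(samples)
  condition <- factor(samples$condition, levels = CONDITIONS)
  if (nlevels(droplevels(condition)) < 2L)
    stop("need both plusUV and minusUV samples to test enrichment")
  replicate <- factor(samples$replicate)
  X <- stats::model.matrix(~condition)
  if (nlevels(replicate) > 1L) {
    Xr <- stats::model.matrix(~condition + replicate)
    # drop replicate columns confounded with condition
    qrX <- qr(Xr)
    if (qrX$rank < ncol(Xr))
      Xr <- Xr[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    # keep the replicate blocking factor only when it leaves residual df;
    # in the minimal 2 +UV vs 1 -UV design the model falls back to the
    # two-sample comparison (moderation supplies the missing df)
    if (nrow(Xr) - qr(Xr)$rank >= 1L && "conditionminusUV" %in% colnames(Xr))
      X <- Xr
  }
  contrast <- as.numeric(colnames(X) == "conditionminusUV") * -1
  if (!any(contrast != 0)) stop("condition coefficient not estimable")
  list(design = X, contrast = contrast)
}

#' Fit per-protein ordinary least squares on observed cells
#'
#' Proteins observed in fewer samples than the rank of the design (or whose
#' observed cells leave the contrast inestimable) are marked untestable
#' rather than raising an error.
#'
#' @param mat normalized (glog2) matrix, proteins x samples.
#' @param design numeric design matrix (samples x coefficients).
#' @param contrast numeric contrast vector over the coefficients.
#' @return list of class `fit_result`: per protein `beta_contrast`, `s_sq`,
#'   `df_resid`, `v_contrast` (unscaled contrast variance), `testable`.
#' @export
fit_linear_models <- function(mat, design, contrast) {
  stopifnot(is.matrix(mat), nrow(design) == ncol(mat),
            length(contrast) == ncol(design))
  G <- nrow(mat)
  beta_c <- rep(NA_real_, G)
  s_sq <- rep(NA_real_, G)
  df_resid <- rep(0L, G)
  v_c <- rep(NA_real_, G)
  testable <- rep(FALSE, G)

  obs_pattern <- apply(!is.na(mat), 1, function(v)
    paste(as.integer(v), collapse = ""))
  for (pat in unique(obs_pattern)) {
    rows <- which(obs_pattern == pat)
    cols <- which(strsplit(pat, "")[[1]] == "1")
    p <- ncol(design)
    if (length(cols) == 0L) next
    Xo <- design[cols, , drop = FALSE]
    qro <- qr(Xo)
    if (qro$rank < p) next  # contrast not estimable on observed cells
    Y <- t(mat[rows, cols, drop = FALSE])       # n_obs x n_rows
    beta <- qr.coef(qro, Y)                     # p x n_rows
    fitted <- Xo %*% beta
    res <- Y - fitted
    df <- length(cols) - p
    # qr.coef returns coefficients in original column order; R (and hence
    # the unscaled covariance) is in pivoted order
    XtXinv <- chol2inv(qr.R(qro))
    piv <- qro$pivot
    v <- drop(t(contrast[piv]) %*% XtXinv %*% contrast[piv])
    beta_c[rows] <- drop(crossprod(contrast, beta))
    df_resid[rows] <- df
    v_c[rows] <- v
    s_sq[rows] <- if (df >= 1L) colSums(res^2) / df else NA_real_
    testable[rows] <- df >= 1L && v > 0
  }
  structure(list(beta_contrast = stats::setNames(beta_c, rownames(mat)),
                 s_sq = s_sq, df_resid = df_resid, v_contrast = v_c,
                 testable = testable),
            class = "fit_result")
}

#' Newton inversion of the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0` by the monotone Newton iteration on
#' `1/trigamma` (trigamma is strictly decreasing and convex in `1/y`).
#'
#' @param x positive values.
#' @return y with `trigamma(y) = x` (elementwise), `Inf` for `x <= 0`.
#' @export
trigamma_inverse <- function(x) {
  out <- rep(NA_real_, length(x))
  out[x <= 0] <- Inf
  big <- is.finite(x) & x > 1e7
  out[big] <- 1 / sqrt(x[big])
  small <- is.finite(x) & x < 1e-6 & x > 0
  out[small] <- 1 / x[small]
  todo <- which(is.na(out) & is.finite(x))
  if (length(todo) > 0L) {
    y <- 0.5 + 1 / x[todo]
    for (i in 1:75) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / x[todo]) / psigamma(y, 2L)
      y <- y + dif
      if (max(-dif / y) < 1e-10) break
    }
    out[todo] <- y
  }
  out
}

#' Estimate the empirical-Bayes variance prior (d0, s0^2)
#'
#' Closed-form moment estimator on the log residual variances: with
#' `z_g = ln(s^2_g)` and `e_g = z_g - digamma(d_g/2) + ln(d_g/2)`, the prior
#' degrees of freedom solve
#' `trigamma(d0/2) = mean((e_g - ebar)^2 * G/(G-1) - trigamma(d_g/2))`
#' (monotone Newton via the trigamma inverse), and
#' `s0^2 = exp(ebar + digamma(d0/2) - ln(d0/2))`. When the right-hand side is
#' non-positive the prior is effectively a point mass: `d0 = Inf`,
#' `s0^2 = exp(ebar)`.
#'
#' @param s_sq per-protein residual variances (NA / zero entries are dropped
#'   from estimation).
#' @param df per-protein residual degrees of freedom.
#' @return list of class `moderation_params`: `d0`, `s0_sq`, `n_used`.
#' @export
estimate_moderation <- function(s_sq, df) {
  stopifnot(length(s_sq) == length(df))
  ok <- is.finite(s_sq) & df >= 1
  if (all(s_sq[ok] == 0)) {
    warning("all residual variances are zero; returning minimal-variance prior")
    return(structure(list(d0 = Inf, s0_sq = .Machine$double.eps,
                          n_used = sum(ok)),
                     class = "moderation_params"))
  }
  ok <- ok & s_sq > 0
  G <- sum(ok)
  if (G < 10L) stop("need >= 10 proteins with positive variance and df >= 1")
  z <- log(s_sq[ok])
  d <- df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  rhs <- mean((e - ebar)^2 * G / (G - 1) - trigamma(d / 2))
  if (rhs <= 0) {
    # no excess spread beyond sampling: point-mass prior at the common
    # variance (the mean of the observed variances, not exp(ebar), whose
    # chi-square log-moment correction would bias a degenerate input)
    d0 <- Inf
    s0_sq <- mean(s_sq[ok])
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_used = G),
            class = "moderation_params")
}

#' Moderated t-test of the enrichment contrast
#'
#' Shrinks per-protein variances toward the empirical-Bayes prior,
#' `s~^2_g = (d0 s0^2 + d_g s^2_g) / (d0 + d_g)`, forms
#' `t~_g = beta_g / (s~_g sqrt(v_g))` and two-sided p-values from the t
#' distribution with `d0 + d_g` degrees of freedom (normal reference when
#' `d0 = Inf`; with `d0 = 0` the statistic reduces to the ordinary t). FDR by
#' [benjamini_hochberg()].
#'
#' @param fit a `fit_result` from [fit_linear_models()].
#' @param mod a `moderation_params` from [estimate_moderation()].
#' @return data.frame: `protein`, `log2fc`, `t_mod`, `df_total`, `p_value`,
#'   `fdr`, `testable`.
#' @export
moderated_test <- function(fit, mod) {
  stopifnot(inherits(fit, "fit_result"), inherits(mod, "moderation_params"))
  d0 <- mod$d0
  s0 <- mod$s0_sq
  d <- fit$df_resid
  s2 <- fit$s_sq
  testable <- fit$testable & !is.na(fit$v_contrast) & fit$v_contrast > 0
  s2_use <- ifelse(is.na(s2), 0, s2)
  if (is.infinite(d0)) {
    s_tilde_sq <- rep(s0, length(d))
    df_total <- rep(Inf, length(d))
  } else if (d0 == 0) {
    s_tilde_sq <- s2_use
    df_total <- d
  } else {
    s_tilde_sq <- (d0 * s0 + d * s2_use) / (d0 + d)
    df_total <- d0 + d
  }
  t_mod <- fit$beta_contrast / sqrt(s_tilde_sq * fit$v_contrast)
  t_mod[!testable] <- NA_real_
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(t_mod)),
              2 * stats::pt(-abs(t_mod), df = df_total))
  p[!testable] <- NA_real_
  data.frame(protein = names(fit$beta_contrast),
             log2fc = unname(fit$beta_contrast),
             t_mod = unname(t_mod), df_total = unname(df_total),
             p_value = unname(p), fdr = benjamini_hochberg(p),
             testable = unname(testable),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Missing p-values are excluded from the number of tests and returned as
#' missing.
#'
#' @param p p-values in `[0, 1]`, NA allowed.
#' @return adjusted values, capped at 1, monotone non-decreasing in p.
#' @export
benjamini_hochberg <- function(p) {
  out <- rep(NA_real_, length(p))
  obs <- !is.na(p)
  if (any(p[obs] < 0 | p[obs] > 1)) stop("p-values must lie in [0, 1]")
  out[obs] <- stats::p.adjust(p[obs], method = "BH")
  out
}

#' Call hit / candidate / no-hit enrichment classes
#'
#' A protein is a *hit* when FDR < `hit_fdr` and its +UV enrichment is at
#' least `log2(hit_fc)`; a *candidate* when (not a hit and) FDR < `cand_fdr`
#' and enrichment at least `log2(cand_fc)`. Enrichment must be positive
#' (+UV over -UV); depletion is never a hit. Untestable-but-quantified
#' proteins are `no_hit`; proteins absent from the assay are `not_detected`.
#'
#' @param table output of [moderated_test()] (columns `log2fc`, `fdr`,
#'   optionally `testable`).
#' @param thresholds a [rp_thresholds()].
#' @param detected logical per row: quantified in this assay (default TRUE).
#' @return the table with an `enrich_class` column added.
#' @export
call_enrichment_classes <- function(table, thresholds = rp_thresholds(),
                                    detected = rep(TRUE, nrow(table))) {
  stopifnot(inherits(thresholds, "rp_thresholds"))
  lfc <- table$log2fc
  fdr <- table$fdr
  ok <- !is.na(lfc) & !is.na(fdr)
  cls <- rep("no_hit", nrow(table))
  cand <- ok & fdr < thresholds$cand_fdr & lfc >= log2(thresholds$cand_fc)
  hit <- ok & fdr < thresholds$hit_fdr & lfc >= log2(thresholds$hit_fc)
  cls[cand] <- "candidate"
  cls[hit] <- "hit"
  cls[!detected] <- "not_detected"
  table$enrich_class <- cls
  table
}

#' Run the full differential enrichment for one (tissue, assay) comparison
#'
#' Convenience wrapper: peptide filter, batch-effect removal on `log2(x+1)`
#' (back-transformed), variance-stabilizing normalization, per-protein linear
#' model with condition + replicate design, moderation, and class calling.
#'
#' @param q a [quant_matrix()] restricted to one (tissue, assay)'s samples
#'   (or pass `tissue`/`assay` to subset here).
#' @param thresholds a [rp_thresholds()].
#' @param strategy VST strategy (see [vst_strata()]).
#' @param tissue,assay optional subsetting.
#' @param clean_batch remove batch effects before normalization.
#' @return a differential table data.frame (one row per protein of the input,
#'   `not_detected` for proteins with no observed cells) with attribute
#'   `"moderation"`.
#' @export
differential_enrichment <- function(q, thresholds = rp_thresholds(),
                                    strategy = "per-tissue-condition",
                                    tissue = NULL, assay = NULL,
                                    clean_batch = TRUE) {
  stopifnot(inherits(q, "quant_matrix"))
  keep <- rep(TRUE, nrow(q$samples))
  if (!is.null(tissue)) keep <- keep & q$samples$tissue %in% tissue
  if (!is.null(assay)) keep <- keep & q$samples$assay %in% assay
  qs <- subset_quant(q, sample_ids = which(keep))
  detected_all <- rowSums(!is.na(qs$intensity)) > 0L

  qf <- peptide_filter(qs, thresholds$min_unique_peptides)
  x <- qf$intensity
  if (clean_batch && length(unique(qf$samples$batch)) > 1L) {
    keep_design <- stats::model.matrix(
      ~condition, data = data.frame(condition = factor(qf$samples$condition,
                                                       levels = CONDITIONS)))
    nbatch <- length(unique(qf$samples$batch))
    # batch effects are only estimable when correcting them leaves residual
    # df; otherwise (e.g. batch == sample) the per-sample VST coefficients
    # absorb additive batch shifts and correction is skipped
    if (nrow(keep_design) - (ncol(keep_design) + nbatch - 1L) >= 1L) {
      logx <- log2(x + 1)
      logx <- tryCatch(
        remove_batch_effects(logx, qf$samples$batch, keep_design),
        error = function(e) {
          message("batch correction skipped: ", conditionMessage(e))
          logx
        })
      x <- pmax(2^logx - 1, 0)
    } else {
      message("batch correction skipped: batch not estimable in this design")
    }
  }
  st <- vst_strata(qf$samples, strategy)
  vst <- variance_stabilizing_transform(x, strata = st$strata,
                                        fit_on = st$fit_on)
  des <- make_design(qf$samples)
  fit <- fit_linear_models(vst$mat, des$design, des$contrast)
  mod <- estimate_moderation(fit$s_sq, fit$df_resid)
  tab <- moderated_test(fit, mod)
  tab$n_unique_peptides <- unname(qf$unique_peptides[tab$protein])
  tab <- call_enrichment_classes(tab, thresholds,
                                 detected = rowSums(!is.na(qf$intensity)) > 0L)

  # re-attach proteins removed upstream (filtered or never observed):
  # detected but untestable -> no_hit; never observed -> not_detected
  removed <- setdiff(rownames(qs$intensity), tab$protein)
  if (length(removed) > 0L) {
    extra <- data.frame(protein = removed, log2fc = NA_real_,
                        t_mod = NA_real_, df_total = NA_real_,
                        p_value = NA_real_, fdr = NA_real_, testable = FALSE,
                        n_unique_peptides = unname(qs$unique_peptides[removed]),
                        enrich_class = ifelse(detected_all[removed], "no_hit",
                                              "not_detected"),
                        stringsAsFactors = FALSE)
    tab <- rbind(tab, extra)
  }
  tab <- tab[match(rownames(qs$intensity), tab$protein), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "moderation") <- mod
  tab
}
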