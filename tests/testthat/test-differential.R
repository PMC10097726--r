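test_that("peptide filter removes exactly the under-supported proteins", {
  q <- make_quant(n_proteins = 3, peptides = c(1L, 2L, 3L))
  expect_message(qf <- peptide_filter(q, 2), "removed")
  expect_equal(rownames(qf$intensity), c("P002", "P003"))
  expect_identical(peptide_filter(qf, 2)$intensity, qf$intensity)
  expect_equal(nrow(peptide_filter(q, 1)$intensity), 3L)
})

test_that("two-group means give the exact contrast and zero residual variance", {
  samples <- make_samples(n_plus = 2, n_minus = 2)
  m <- rbind(P1 = c(5, 5, 3, 3), P2 = c(1, 1, 1, 1))
  colnames(m) <- samples$sample_id
  des <- make_design(samples)
  fit <- fit_linear_models(m, des$design, des$contrast)
  expect_equal(unname(fit$beta_contrast), c(2, 0))
  expect_equal(fit$s_sq, c(0, 0), tolerance = 1e-12)
})

test_that("coefficients match a normal-equations oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    repeat {
      X <- cbind(1, rnorm(n), sample(0:1, n, replace = TRUE))
      if (qr(X)$rank == 3L) break
    }
    y <- matrix(rnorm(3 * n), 3, n,
                dimnames = list(paste0("P", 1:3), paste0("s", 1:n)))
    y[1, sample(n, 1)] <- NA
    ctr <- c(0, 1, -0.5)
    fit <- fit_linear_models(y, X, ctr)
    for (i in 1:3) {
      obs <- !is.na(y[i, ])
      Xo <- X[obs, ]
      if (qr(Xo)$rank < ncol(Xo)) {
        expect_false(fit$testable[i])  # inestimable on observed cells
        next
      }
      beta <- solve(t(Xo) %*% Xo, t(Xo) %*% y[i, obs])
      expect_equal(unname(fit$beta_contrast[i]), drop(ctr %*% beta),
                   tolerance = 1e-10)
      df <- sum(obs) - ncol(X)
      if (df >= 1) {
        rss <- sum((y[i, obs] - Xo %*% beta)^2)
        expect_equal(fit$s_sq[i], rss / df, tolerance = 1e-10)
        expect_equal(fit$v_contrast[i],
                     drop(t(ctr) %*% solve(t(Xo) %*% Xo) %*% ctr),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("constant replicate factor reduces to the two-sample comparison", {
  samples <- make_samples(n_plus = 2, n_minus = 2)
  samples$replicate <- 1L
  des <- make_design(samples)
  expect_equal(ncol(des$design), 2L)
  m <- matrix(c(6, 4, 2, 2), 1, 4,
              dimnames = list("P1", samples$sample_id))
  fit <- fit_linear_models(m, des$design, des$contrast)
  expect_equal(unname(fit$beta_contrast), 5 - 2)
})

test_that("proteins observed below design rank are untestable, not errors", {
  samples <- make_samples(n_plus = 2, n_minus = 1)
  m <- rbind(P1 = c(4, 4.5, 2), P2 = c(4, NA, NA))
  colnames(m) <- samples$sample_id
  des <- make_design(samples)
  fit <- fit_linear_models(m, des$design, des$contrast)
  expect_true(fit$testable[1])
  expect_false(fit$testable[2])
  expect_true(is.na(fit$beta_contrast[2]))
})

test_that("trigamma inverse round-trips over a wide grid", {
  x <- trigamma(c(0.05, 0.2, 0.7, 1, 3, 10, 80, 1500))
  expect_equal(trigamma(trigamma_inverse(x)), x, tolerance = 1e-8)
})

test_that("moderation estimator: zero spread gives the infinite-df prior", {
  mod <- estimate_moderation(rep(2.5, 50), rep(3, 50))
  expect_identical(mod$d0, Inf)
  expect_equal(mod$s0_sq, 2.5, tolerance = 1e-9)
})

test_that("moderation estimator recovers planted (d0, s0^2) and matches limma", {
  skip_if_not_installed("limma")
  set.seed(12)
  d0 <- 4; s0 <- 1; G <- 5000; dg <- 3
  ok_d0 <- 0; ok_s0 <- 0; reps <- 20
  for (i in seq_len(reps)) {
    s2 <- s0 * d0 / rchisq(G, d0) * rchisq(G, dg) / dg
    mod <- estimate_moderation(s2, rep(dg, G))
    if (mod$d0 >= 3 && mod$d0 <= 5.3) ok_d0 <- ok_d0 + 1
    if (mod$s0_sq >= 0.9 && mod$s0_sq <= 1.1) ok_s0 <- ok_s0 + 1
  }
  expect_gte(ok_d0, 0.9 * reps)
  expect_gte(ok_s0, 0.9 * reps)

  # independent cross-check on one draw
  set.seed(13)
  s2 <- s0 * d0 / rchisq(G, d0) * rchisq(G, dg) / dg
  mine <- estimate_moderation(s2, rep(dg, G))
  lim <- limma::fitFDist(s2, df1 = rep(dg, G))
  expect_equal(mine$d0, lim$df2, tolerance = 1e-6)
  expect_equal(mine$s0_sq, lim$scale, tolerance = 1e-6)
})

test_that("moderated t has the stated closed-form limits", {
  samples <- make_samples(n_plus = 3, n_minus = 2)
  set.seed(14)
  m <- matrix(rnorm(40, 10), 8, 5,
              dimnames = list(paste0("P", 1:8), samples$sample_id))
  des <- make_design(samples)
  fit <- fit_linear_models(m, des$design, des$contrast)

  mod0 <- structure(list(d0 = 0, s0_sq = 1, n_used = 8),
                    class = "moderation_params")
  t_ord <- fit$beta_contrast / sqrt(fit$s_sq * fit$v_contrast)
  tab0 <- moderated_test(fit, mod0)
  expect_equal(tab0$t_mod, unname(t_ord), tolerance = 1e-12)
  expect_equal(tab0$p_value,
               unname(2 * pt(-abs(t_ord), fit$df_resid)), tolerance = 1e-12)

  modInf <- structure(list(d0 = Inf, s0_sq = 0.8, n_used = 8),
                      class = "moderation_params")
  tabI <- moderated_test(fit, modInf)
  expect_equal(tabI$t_mod,
               unname(fit$beta_contrast / sqrt(0.8 * fit$v_contrast)),
               tolerance = 1e-12)
  expect_equal(tabI$p_value, 2 * pnorm(-abs(tabI$t_mod)), tolerance = 1e-12)
})

test_that("moderated statistics agree with limma on a complete design", {
  skip_if_not_installed("limma")
  set.seed(15)
  samples <- make_samples(n_plus = 3, n_minus = 3)
  G <- 400
  m <- matrix(rnorm(G * 6, 12, 1), G, 6,
              dimnames = list(sprintf("P%03d", 1:G), samples$sample_id))
  m[1:60, samples$condition == "plusUV"] <- m[1:60, samples$condition ==
                                                "plusUV"] + 1.5
  des <- make_design(samples)
  fit <- fit_linear_models(m, des$design, des$contrast)
  mod <- estimate_moderation(fit$s_sq, fit$df_resid)
  tab <- moderated_test(fit, mod)

  lfit <- limma::lmFit(m, des$design)
  lfit <- limma::contrasts.fit(lfit, contrasts = des$contrast)
  eb <- limma::eBayes(lfit)
  expect_equal(tab$log2fc, unname(lfit$coefficients[, 1]), tolerance = 1e-9)
  expect_equal(tab$t_mod, unname(eb$t[, 1]), tolerance = 1e-6)
  expect_equal(tab$p_value, unname(eb$p.value[, 1]), tolerance = 1e-6)
})

test_that("moderation shrinks the spread of the statistic", {
  set.seed(16)
  samples <- make_samples(n_plus = 2, n_minus = 2)
  G <- 800
  # heavy-tailed variances
  sdv <- sqrt(1 / rchisq(G, 2) * 2)
  m <- matrix(rnorm(G * 4, 0, sdv), G, 4,
              dimnames = list(sprintf("P%03d", 1:G), samples$sample_id))
  des <- make_design(samples)
  fit <- fit_linear_models(m, des$design, des$contrast)
  mod <- estimate_moderation(fit$s_sq, fit$df_resid)
  tab <- moderated_test(fit, mod)
  t_ord <- fit$beta_contrast / sqrt(fit$s_sq * fit$v_contrast)
  ok <- is.finite(t_ord) & !is.na(tab$t_mod)
  expect_lt(var(tab$t_mod[ok]), var(t_ord[ok]))
})

test_that("BH adjustment matches the brute-force step-up and handles NAs", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-12)
  }
  p <- c(0.01, NA, 0.04)
  adj <- benjamini_hochberg(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], bh_oracle(p[c(1, 3)]))  # m excludes missing
  expect_true(all(benjamini_hochberg(runif(100)) <= 1))
})

test_that("hit and candidate calling follows the FDR/fold-change rules", {
  tab <- data.frame(
    protein = paste0("P", 1:6),
    log2fc = c(1.5, 0.8, -2.0, log2(1.5), 3, 0.2),
    fdr = c(0.01, 0.10, 0.01, 0.19, 0.30, 0.01),
    stringsAsFactors = FALSE)
  out <- call_enrichment_classes(tab, rp_thresholds())
  expect_equal(out$enrich_class,
               c("hit",        # fdr .01, lfc 1.5
                 "candidate",  # fdr .10, fc 2^0.8 > 1.5
                 "no_hit",     # depletion is not enrichment
                 "candidate",  # boundary fc = 1.5 qualifies
                 "no_hit",     # fdr too large
                 "no_hit"))    # fc too small
  out2 <- call_enrichment_classes(tab, rp_thresholds(),
                                  detected = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                                               FALSE))
  expect_equal(out2$enrich_class[6], "not_detected")
})

test_that("type-I error of the moderated test is calibrated on null data", {
  set.seed(18)
  reps <- 40
  G <- 500
  frac <- numeric(reps)
  samples <- make_samples(n_plus = 2, n_minus = 1)
  des <- make_design(samples)
  for (r in seq_len(reps)) {
    m <- matrix(rnorm(G * 3), G, 3,
                dimnames = list(sprintf("P%03d", 1:G), samples$sample_id))
    fit <- fit_linear_models(m, des$design, des$contrast)
    mod <- estimate_moderation(fit$s_sq, fit$df_resid)
    tab <- moderated_test(fit, mod)
    frac[r] <- mean(tab$p_value < 0.05, na.rm = TRUE)
  }
  expect_gt(mean(frac), 0.035)
  expect_lt(mean(frac), 0.065)
})
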