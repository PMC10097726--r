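test_that("RNA-content adjustment divides by the right biotype content", {
  samples <- rbind(make_samples("brain", "eric", 1, 1),
                   make_samples("kidney", "nonpolya_ric", 1, 1))
  m <- matrix(100, 2, 4,
              dimnames = list(c("P1", "P2"), samples$sample_id))
  rna <- simulated_rna_content()
  out <- rna_adjust_signal(m, samples, rna)
  expect_equal(out[1, 1], 100 / rna$polya_ug_per_mg_protein[1])
  expect_equal(out[1, 3], 100 / rna$nonpolya_ug_per_mg_protein[2])

  # doubling one tissue's content halves that tissue's adjusted signal
  rna2 <- rna
  rna2$polya_ug_per_mg_protein[1] <- 2 * rna$polya_ug_per_mg_protein[1]
  out2 <- rna_adjust_signal(m, samples, rna2)
  expect_equal(out2[, 1:2], out[, 1:2] / 2)
  expect_equal(out2[, 3:4], out[, 3:4])

  expect_error(rna_adjust_signal(m, samples, rna[rna$tissue != "brain", ]),
               "brain")
})

test_that("mean signal summary reproduces the printed organ ratio arithmetic", {
  # construct per-organ signals whose means are the printed values
  means <- c(brain = 1.0e7, kidney = 5.3e7, liver = 1.4e7)
  m <- rbind(A = as.numeric(means), B = as.numeric(means))
  colnames(m) <- names(means)
  res <- mean_signal_summary(m, c("A", "B"), colnames(m))
  expect_equal(unname(res$means), unname(means))
  expect_equal(res$ratios["kidney", "brain"], 5.3)
  expect_equal(res$ratios["kidney", "liver"], 5.3 / 1.4, tolerance = 1e-12)
  expect_equal(round(res$ratios["kidney", "liver"], 1), 3.8)
  expect_equal(res$ratios["liver", "brain"], 1.4)

  # identical groups: all ratios 1
  same <- matrix(7, 2, 4, dimnames = list(c("A", "B"), paste0("s", 1:4)))
  expect_true(all(mean_signal_summary(same, c("A", "B"),
                                      c("g1", "g1", "g2", "g2"))$ratios == 1))

  # brute-force oracle on random data with missing cells
  set.seed(41)
  m2 <- matrix(runif(40, 1, 100), 8, 5,
               dimnames = list(sprintf("P%d", 1:8), paste0("s", 1:5)))
  m2[2, 3] <- NA
  grp <- c("a", "a", "b", "b", "b")
  res2 <- mean_signal_summary(m2, rownames(m2)[1:6], grp)
  bf_a <- mean(m2[1:6, grp == "a"], na.rm = TRUE)
  bf_b <- mean(m2[1:6, grp == "b"], na.rm = TRUE)
  expect_equal(unname(res2$means), c(bf_a, bf_b), tolerance = 1e-12)
  expect_equal(res2$ratios["a", "b"], bf_a / bf_b, tolerance = 1e-12)
  expect_error(mean_signal_summary(m2, character(0), grp), "empty")
})

test_that("relative abundance uses the linear-scale arithmetic row mean", {
  e <- matrix(c(1, 2, 4), 1, 3,
              dimnames = list("P1", c("e1", "e2", "e3")))
  i <- matrix(c(3, 3), 1, 2, dimnames = list("P1", c("i1", "i2")))
  out <- relative_abundance_matrix(e, i)
  expect_equal(round(out[1, 1:3], 3), c(e1 = -1.222, e2 = -0.222, e3 = 0.778))
  expect_equal(out[1, 4:5], c(i1 = 0, i2 = 0))

  # constant rows are all zero; family rows sum to a mean-convention constant
  e2 <- matrix(5, 2, 3, dimnames = list(c("A", "B"), c("e1", "e2", "e3")))
  i2 <- matrix(2, 2, 2, dimnames = list(c("A", "B"), c("i1", "i2")))
  expect_true(all(relative_abundance_matrix(e2, i2) == 0))
  set.seed(42)
  e3 <- matrix(runif(12, 1, 9), 4, 3,
               dimnames = list(paste0("P", 1:4), c("e1", "e2", "e3")))
  i3 <- matrix(runif(8, 1, 9), 4, 2,
               dimnames = list(paste0("P", 1:4), c("i1", "i2")))
  out3 <- relative_abundance_matrix(e3, i3)
  # sum of 2^x per family row = n_family (arithmetic-mean convention)
  expect_equal(rowSums(2^out3[, 1:3]), rep(3, 4), ignore_attr = TRUE)
  expect_equal(rowSums(2^out3[, 4:5]), rep(2, 4), ignore_attr = TRUE)

  # rows with missing cells are dropped with a message
  e3[1, 1] <- NA
  expect_message(out4 <- relative_abundance_matrix(e3, i3), "dropped")
  expect_equal(nrow(out4), 3L)
})

test_that("average-linkage clustering matches the brute-force oracle", {
  set.seed(43)
  m <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("P%02d", 1:20), paste0("s", 1:6)))
  cl <- cluster_rbps(m, k = 3)
  d <- as.dist(1 - cor(t(m[order(rownames(m)), ])))
  expect_equal(sort(cl$hclust$height), sort(average_linkage_heights(d)),
               tolerance = 1e-10)

  # identical rows merge first at height 0
  m2 <- rbind(X = c(1, 2, 3, 4), Y = c(1, 2, 3, 4), Z = c(4, 1, 9, 2))
  cl2 <- cluster_rbps(m2, k = 2)
  expect_equal(min(cl2$hclust$height), 0, tolerance = 1e-12)
  expect_equal(cl2$labels[["X"]], cl2$labels[["Y"]])

  # perfectly correlated pair clusters together against an anticorrelated row
  m3 <- rbind(A = c(1, 2, 3), B = c(2, 4, 6), C = c(3, 2, 1))
  cl3 <- cluster_rbps(m3, k = 2)
  expect_equal(cl3$labels[["A"]], cl3$labels[["B"]])
  expect_false(cl3$labels[["A"]] == cl3$labels[["C"]])

  # permutation invariance of the partition
  perm <- sample(nrow(m))
  clp <- cluster_rbps(m[perm, ], k = 3)
  expect_equal(clp$labels[rownames(m)], cl$labels[rownames(m)])
  expect_error(cluster_rbps(m[1, , drop = FALSE]), ">= 2")
})

test_that("replicate correlation equals the textbook formula and is symmetric", {
  set.seed(44)
  m <- matrix(rnorm(60, 10), 20, 3,
              dimnames = list(sprintf("P%02d", 1:20), c("a", "b", "c")))
  m[3, 1] <- NA
  out <- replicate_correlation(m, data.frame(s1 = "a", s2 = "b"))
  ok <- !is.na(m[, "a"])
  x <- m[ok, "a"]; y <- m[ok, "b"]
  r_bf <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_bf, tolerance = 1e-12)
  rev_ <- replicate_correlation(m, data.frame(s1 = "b", s2 = "a"))
  expect_equal(out$r, rev_$r)
  # scale invariance
  out_scaled <- replicate_correlation(sweep(m, 2, c(3, 7, 1), "*"),
                                      data.frame(s1 = "a", s2 = "b"))
  expect_equal(out_scaled$r, out$r, tolerance = 1e-12)

  expect_equal(replicate_correlation(cbind(m[, 1, drop = FALSE],
                                           d = m[, 1]),
                                     data.frame(s1 = "a", s2 = "d"))$r, 1)
  expect_equal(replicate_correlation(cbind(m[, 1, drop = FALSE],
                                           d = -m[, 1]),
                                     data.frame(s1 = "a", s2 = "d"))$r, -1)
  m_small <- m
  m_small[4:20, "c"] <- NA
  m_small[1:2, "c"] <- NA
  expect_warning(res <- replicate_correlation(m_small,
                                              data.frame(s1 = "a", s2 = "c")),
                 "fewer than")
  expect_true(is.na(res$r))
})

test_that("binding-vs-abundance decoupling classes follow the definitions", {
  ce <- data.frame(protein = c("A", "B", "C", "D"),
                   log2fc = c(2, 2, 0.1, 0.3), fdr = c(0.01, 0.01, 0.9, 0.6),
                   stringsAsFactors = FALSE)
  ab <- data.frame(protein = c("A", "B", "C", "D"),
                   log2fc = c(0.1, 2, 2, 0.2), fdr = c(0.9, 0.01, 0.01, 0.7),
                   stringsAsFactors = FALSE)
  out <- binding_vs_abundance(ce, ab)
  expect_equal(out$decoupling_class,
               c("binding_only", "concordant", "abundance_only", "neither"))
})

test_that("planted binding-only proteins are recovered with recall >= 0.8", {
  set.seed(45)
  G <- 400
  binding_only <- sample(G, 40)
  base_fc <- rnorm(G, 0, 0.2)
  e_fc <- base_fc; e_fc[binding_only] <- rnorm(40, 2.5, 0.3)
  # simulate moderated outputs: tight fdr when the effect is large
  mk <- function(fc) data.frame(protein = sprintf("P%03d", 1:G), log2fc = fc,
                                fdr = ifelse(abs(fc) > 1, 0.001, 0.8),
                                stringsAsFactors = FALSE)
  out <- binding_vs_abundance(mk(e_fc), mk(base_fc))
  rec <- mean(out$decoupling_class[binding_only] == "binding_only")
  expect_gte(rec, 0.8)
})
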