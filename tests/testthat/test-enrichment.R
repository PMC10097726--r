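test_that("one-tailed Fisher p equals hypergeometric enumeration", {
  # the anchor table
  fg <- c(sprintf("F%02d", 1:10))
  bg <- c(fg, sprintf("B%02d", 1:90))
  term <- c(fg[1:8], sprintf("B%02d", 1:10))
  res <- fisher_enrichment(fg, bg, list(t = term), tail = "greater")
  expect_equal(unlist(res[, c("a", "b", "c", "d")], use.names = FALSE),
               c(8L, 2L, 10L, 80L))
  expect_equal(res$p_value, fisher_oracle_greater(8, 2, 10, 80),
               tolerance = 1e-12)

  # sweep over all tables with small margins
  for (r1 in 0:12) for (r2 in 0:12) for (a in 0:r1) for (c_ in 0:r2) {
    b <- r1 - a; d <- r2 - c_
    if (a + c_ == 0) next
    p_mine <- phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
    expect_equal(p_mine, fisher_oracle_greater(a, b, c_, d),
                 tolerance = 1e-12)
  }
})

test_that("two-sided Fisher p matches fisher.test and OR handles zeros", {
  fg <- sprintf("F%02d", 1:12)
  bg <- c(fg, sprintf("B%02d", 1:30))
  term <- c(fg[1:6], sprintf("B%02d", 1:3))
  res <- fisher_enrichment(fg, bg, list(t = term), tail = "two_sided")
  ref <- fisher.test(matrix(c(6, 6, 3, 27), 2, byrow = TRUE))$p.value
  expect_equal(res$p_value, ref, tolerance = 1e-12)

  # equal proportions give OR = 1
  fg2 <- c("A1", "A2")
  bg2 <- c(fg2, "B1", "B2")
  res2 <- fisher_enrichment(fg2, bg2, list(t = c("A1", "B1")))
  expect_equal(res2$odds_ratio, 1)

  # zero cell: Haldane correction
  res3 <- fisher_enrichment(fg2, bg2, list(t = fg2))
  expect_equal(res3$odds_ratio, (2.5 * 2.5) / (0.5 * 0.5))

  expect_error(fisher_enrichment(character(0), bg2, list(t = "A1")), "empty")
  expect_error(fisher_enrichment(c("X", fg2), bg2, list(t = "A1")), "subset")
  # terms never seen are skipped
  res4 <- fisher_enrichment(fg2, bg2, list(t = "A1", ghost = "Z9"))
  expect_equal(res4$term, "t")
})

test_that("doubling all cells preserves OR and sharpens one-tailed p", {
  set.seed(61)
  for (i in 1:25) {
    a <- sample(1:10, 1); b <- sample(0:10, 1)
    c_ <- sample(0:10, 1); d <- sample(1:20, 1)
    or1 <- if (min(a, b, c_, d) == 0) NA else (a * d) / (b * c_)
    p1 <- fisher_oracle_greater(a, b, c_, d)
    p2 <- fisher_oracle_greater(2 * a, 2 * b, 2 * c_, 2 * d)
    if (!is.na(or1) && or1 > 1) expect_lte(p2, p1 + 1e-12)
    if (!is.na(or1))
      expect_equal((2 * a * 2 * d) / (2 * b * 2 * c_), or1)
  }
})

test_that("cofactor/domain enrichment reports hand-countable proportions", {
  # 10-protein fixture: 6 enzyme hits (4 with CoA), 4 contrast enzymes
  # (1 with CoA)
  catalog <- validate_annotation_catalog(data.frame(
    protein = sprintf("E%02d", 1:10), known_rbp = FALSE,
    protein_class = "metabolite interconversion enzyme",
    cofactors = c("CoA", "CoA", "CoA", "CoA", "", "",
                  "CoA", "", "", ""),
    domains = c(rep("NT_binding_domain", 2), rep("", 8)),
    stringsAsFactors = FALSE))
  hits <- sprintf("E%02d", 1:6)
  eluate <- hits
  inputs <- sprintf("E%02d", 1:10)
  res <- cofactor_domain_enrichment(hits, eluate, inputs, catalog)
  coa <- res[res$category == "CoA" & res$kind == "cofactor", ]
  expect_equal(coa$fg_with, 4L); expect_equal(coa$fg_total, 6L)
  expect_equal(coa$bg_with, 1L); expect_equal(coa$bg_total, 4L)
  expect_equal(coa$fg_prop, 4 / 6)
  expect_equal(coa$p_value,
               fisher.test(matrix(c(4, 2, 1, 3), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)

  # extreme fixture: all RBP-enzymes and no contrast enzymes carry CoA
  cat2 <- catalog
  cat2$cofactors <- c(rep("CoA", 6), rep("", 4))
  res2 <- cofactor_domain_enrichment(hits, eluate, inputs, cat2)
  coa2 <- res2[res2$category == "CoA" & res2$kind == "cofactor", ]
  # two-sided point-probability p of the extreme table = one-tailed sum
  expect_equal(coa2$p_value,
               fisher.test(matrix(c(6, 0, 0, 4), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
})

test_that("null catalogs stay calibrated across categories", {
  set.seed(62)
  n_sig <- 0L; n_tests <- 0L
  for (i in 1:100) {
    n <- 80
    catalog <- validate_annotation_catalog(data.frame(
      protein = sprintf("P%02d", 1:n), known_rbp = FALSE,
      protein_class = "metabolite interconversion enzyme",
      cofactors = ifelse(runif(n) < 0.3, "ATP", ""),
      stringsAsFactors = FALSE))
    hits <- sample(catalog$protein, 30)
    res <- cofactor_domain_enrichment(hits, hits, catalog$protein, catalog)
    n_sig <- n_sig + sum(res$p_value < 0.05)
    n_tests <- n_tests + nrow(res)
  }
  expect_lte(n_sig / n_tests, 0.05 + 2 * sqrt(0.05 * 0.95 / n_tests))
})

test_that("catalytic class profile counts partition the groups", {
  catalog <- validate_annotation_catalog(data.frame(
    protein = sprintf("E%02d", 1:12), known_rbp = FALSE,
    protein_class = "metabolite interconversion enzyme",
    catalytic_type = c(rep("ligase", 3), rep("hydrolase", 4),
                       rep("transferase", 5)),
    catalytic_subtype = NA_character_, stringsAsFactors = FALSE))
  rbp <- sprintf("E%02d", 1:5)      # all 3 ligases + 2 hydrolases
  other <- sprintf("E%02d", 6:12)
  prof <- catalytic_class_profile(rbp, other, catalog)
  expect_equal(sum(prof$rbp_n), length(rbp))
  expect_equal(sum(prof$other_n), length(other))
  expect_false(any(prof$corrected))
  # ligases only among RBP-enzymes: smallest p of all classes
  expect_equal(prof$class[which.min(prof$p_value)], "ligase")

  # identical class distributions: OR = 1 everywhere
  cat2 <- catalog
  rbp2 <- c("E01", "E04", "E08")     # 1 of each type
  oth2 <- c("E02", "E05", "E09")
  prof2 <- catalytic_class_profile(rbp2, oth2, cat2)
  expect_true(all(prof2$odds_ratio == 1))
})

test_that("pathway RBP fractions equal brute-force set intersections", {
  pw <- list(glycolysis = sprintf("G%02d", 1:10),
             tca = sprintf("T%02d", 1:4))
  hits <- list(brain = c(sprintf("G%02d", 1:6), "T01"),
               liver = sprintf("G%02d", 1:10))
  out <- pathway_rbp_fraction(pw, hits)
  expect_equal(out$fraction[out$pathway == "glycolysis" &
                              out$organ == "brain"], 0.6)
  expect_equal(out$fraction[out$pathway == "glycolysis" &
                              out$organ == "liver"], 1)
  expect_equal(out$fraction[out$pathway == "tca" & out$organ == "brain"],
               0.25)
  # restricted denominator
  inputs <- list(brain = sprintf("G%02d", 1:5), liver = sprintf("G%02d", 1:10))
  out2 <- pathway_rbp_fraction(pw, hits, inputs)
  expect_equal(out2$fraction[out2$pathway == "glycolysis" &
                               out2$organ == "brain"], 1)
  expect_true(is.na(out2$fraction[out2$pathway == "tca" &
                                    out2$organ == "brain"]))

  set.seed(63)
  for (i in 1:10) {
    members <- sample(sprintf("P%02d", 1:40), 15)
    hit <- sample(sprintf("P%02d", 1:40), 20)
    got <- pathway_rbp_fraction(list(x = members), list(o = hit))
    expect_equal(got$fraction, length(intersect(members, hit)) / 15)
  }
})
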