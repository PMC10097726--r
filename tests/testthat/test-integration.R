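# exhaustive biotype truth table over all 4 x 4 class pairs and both modes;
# "q" marks classes that qualify under the mode
biotype_truth_table <- function(mode) {
  qualifying <- if (mode == "hit_only") "hit" else c("hit", "candidate")
  classes <- c("hit", "candidate", "no_hit", "not_detected")
  grid <- expand.grid(polya = classes, nonpolya = classes,
                      stringsAsFactors = FALSE)
  expected <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pq <- grid$polya[i] %in% qualifying
    nq <- grid$nonpolya[i] %in% qualifying
    expected[i] <-
      if (pq && nq) "dual"
      else if (pq && grid$nonpolya[i] == "not_detected") "exclusive_polya"
      else if (pq) "polya_unresolved"
      else if (nq && grid$polya[i] == "not_detected") "exclusive_nonpolya"
      else if (nq) "nonpolya_unresolved"
      else "none"
  }
  cbind(grid, expected = expected)
}

test_that("biotype classification matches the exhaustive truth table", {
  for (mode in c("hit_only", "hit_or_candidate")) {
    tt <- biotype_truth_table(mode)
    got <- classify_biotype(tt$polya, tt$nonpolya, mode)
    expect_equal(got, tt$expected, info = mode)
  }
  # the documented anchor cases
  expect_equal(classify_biotype("hit", "not_detected"), "exclusive_polya")
  expect_equal(classify_biotype("candidate", "hit", "hit_or_candidate"),
               "dual")
  expect_equal(classify_biotype("hit", "no_hit"), "polya_unresolved")
  expect_error(classify_biotype("hit", "banana"), "unknown")
})

test_that("atlas assembly honours modes and the extra exclusion list", {
  pt <- list(liver = data.frame(protein = c("A", "B", "C"),
                                enrich_class = c("hit", "candidate", "no_hit"),
                                stringsAsFactors = FALSE))
  nt <- list(liver = data.frame(protein = c("B", "D"),
                                enrich_class = c("hit", "hit"),
                                stringsAsFactors = FALSE))
  atlas <- build_binding_atlas(pt, nt, mode = "hit_or_candidate")
  row <- function(p) atlas[atlas$protein == p, ]
  expect_equal(row("A")$biotype_class, "exclusive_polya")
  expect_equal(row("B")$biotype_class, "dual")
  expect_equal(row("D")$biotype_class, "exclusive_nonpolya")
  expect_equal(row("C")$biotype_class, "none")
  # A detected in a deeper non-poly(A) run: no longer exclusive
  atlas2 <- build_binding_atlas(pt, nt, mode = "hit_or_candidate",
                                extra_nonpolya_detected = "A")
  expect_equal(atlas2[atlas2$protein == "A", "biotype_class"],
               "polya_unresolved")
})

test_that("cross-organ overlap equals brute-force membership enumeration", {
  sets <- list(brain = c("A", "B", "C"), kidney = c("B", "C", "D"),
               liver = c("C", "E"))
  ov <- cross_organ_overlap(sets)
  expect_equal(ov$count[ov$region == "brain&kidney&liver"], 1L)  # C
  expect_equal(ov$count[ov$region == "brain&kidney"], 1L)        # B
  expect_equal(sum(ov$count), length(unique(unlist(sets))))

  # identical sets: everything in the all-organ region
  same <- list(a = c("X", "Y"), b = c("X", "Y"))
  ovs <- cross_organ_overlap(same)
  expect_equal(ovs$count[ovs$region == "a&b"], 2L)
  expect_equal(sum(ovs$count), 2L)
  # disjoint sets: only organ-exclusive regions
  dis <- cross_organ_overlap(list(a = "X", b = "Y"))
  expect_equal(dis$count[dis$region %in% c("a", "b")], c(1L, 1L))
  expect_equal(dis$count[dis$region == "a&b"], 0L)

  set.seed(31)
  for (i in 1:10) {
    rs <- lapply(1:3, function(j) sample(sprintf("P%02d", 1:30),
                                         sample(5:20, 1)))
    names(rs) <- c("o1", "o2", "o3")
    ov <- cross_organ_overlap(rs)
    # brute force: classify each protein of the union by its membership
    un <- unique(unlist(rs))
    key <- vapply(un, function(p)
      paste(names(rs)[vapply(rs, function(s) p %in% s, logical(1))],
            collapse = "&"), character(1))
    bf <- table(key)
    for (region in names(bf))
      expect_equal(ov$count[ov$region == region], unname(as.integer(bf[region])))
    expect_equal(sum(ov$count), length(un))
  }
  expect_error(cross_organ_overlap(sets, organs = c("brain", "lung")),
               "unknown organ")
})

test_that("novel RBP identification recovers the planted novel fraction", {
  set.seed(32)
  proteins <- sprintf("P%03d", 1:100)
  hits <- list(brain = proteins[1:40], kidney = proteins[21:60])
  novel_planted <- proteins[seq(1, 60, by = 10)]  # known_rbp = FALSE
  catalog <- validate_annotation_catalog(data.frame(
    protein = proteins,
    known_rbp = !(proteins %in% novel_planted), stringsAsFactors = FALSE))
  out <- identify_novel_rbps(hits, catalog)
  expect_setequal(out$novel, novel_planted)
  expect_equal(sum(out$by_region$count), length(novel_planted))

  # all hits annotated known: empty novel set
  cat_all <- transform(catalog, known_rbp = TRUE)
  expect_length(identify_novel_rbps(hits, cat_all)$novel, 0L)
  # hits missing from the catalog produce a warning, not novelty
  expect_warning(identify_novel_rbps(list(x = c("GHOST", proteins[1])),
                                     catalog), "absent")
})

test_that("cell-line presence histogram matches brute force and is monotone", {
  catalog <- validate_annotation_catalog(data.frame(
    protein = c("A", "B", "C"), known_rbp = TRUE,
    cell_lines_detected = c(paste(sprintf("CL%02d", 1:10), collapse = ";"),
                            "CL01;CL02", ""), stringsAsFactors = FALSE))
  prof <- cell_line_presence_profile(c("A", "B", "C"), catalog, k_max = 10)
  expect_equal(prof$count, c(2L, 2L, rep(1L, 8)))
  expect_true(all(diff(prof$count) <= 0))
  empty <- cell_line_presence_profile("C", catalog, k_max = 3)
  expect_equal(empty$count, rep(0L, 3))

  set.seed(33)
  mats <- matrix(runif(50 * 8) < 0.4, 50, 8)
  rownames(mats) <- sprintf("P%02d", 1:50)
  cat2 <- validate_annotation_catalog(data.frame(
    protein = rownames(mats), known_rbp = TRUE,
    cell_lines_detected = apply(mats, 1, function(v)
      paste(sprintf("CL%02d", which(v)), collapse = ";")),
    stringsAsFactors = FALSE))
  prof2 <- cell_line_presence_profile(rownames(mats), cat2, k_max = 8)
  bf <- vapply(1:8, function(k) sum(rowSums(mats) >= k), integer(1))
  expect_equal(prof2$count, bf)
})

test_that("missing-in-organ cascade recovers planted stage sizes and nests", {
  # construct sets with known stage sizes 20 / 5 / 10 / 5
  common <- sprintf("C%02d", 1:25)
  polya_hits <- list(o1 = c(common[21:25], "X1"), o2 = "X2")  # 20 absent
  nonpolya_hits <- list(o1 = common[1:5])                     # 5 rescued
  # of the 15 remaining: 5 undetected anywhere, 5 in all inputs, 5 partial
  inputs <- list(o1 = c(common[6:15], "Y"), o2 = common[6:10],
                 o3 = common[6:10])
  cas <- missing_in_organ_cascade(common, polya_hits, nonpolya_hits, inputs)
  expect_length(cas$stage1_absent_polya, 20L)
  expect_length(cas$detected_nonpolya, 5L)
  expect_length(cas$stage2_remaining, 15L)
  expect_length(cas$undetected_in_inputs, 5L)
  expect_length(cas$final_focus, 5L)
  expect_length(cas$partially_detected, 5L)
  # nesting and disjoint partition of stage 2
  expect_true(all(cas$stage2_remaining %in% cas$stage1_absent_polya))
  expect_setequal(c(cas$undetected_in_inputs, cas$partially_detected,
                    cas$final_focus), cas$stage2_remaining)

  none <- missing_in_organ_cascade(character(0), polya_hits, nonpolya_hits,
                                   inputs)
  expect_true(all(lengths(none) == 0L))
})

test_that("commonly identified cell-line RBPs honour the report-fraction rule", {
  catalog <- validate_annotation_catalog(data.frame(
    protein = c("A", "B", "C"), known_rbp = TRUE,
    atlas_report_fraction = c(0.9, 0.5, 0.2), stringsAsFactors = FALSE))
  expect_equal(common_cell_line_rbps(catalog), c("A", "B"))
})
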