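make_lognrq <- function(m) {
  dimnames(m) <- list(paste0("miR-", seq_len(nrow(m))),
                      paste0("S", seq_len(ncol(m))))
  m
}

test_that("identical groups give t = 0, p = 1, n.s.", {
  m <- make_lognrq(matrix(rep(c(0.1, 0.2, 0.3), 2), 1, 6, byrow = TRUE))
  ann <- make_annotations(colnames(m), rep(c("NGT", "T2D"), each = 3))
  res <- run_contrasts(m, ann, contrasts = list(T2D_vs_NGT = c("T2D", "NGT")))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$category, "n.s.")
  expect_equal(res$direction, 0)
})

test_that("the pooled-variance t matches the closed-form computation", {
  m <- make_lognrq(matrix(c(1, 2, 3, 4, 5, 6), 1, 6))
  ann <- make_annotations(colnames(m), rep(c("NGT", "T2D"), each = 3))
  res <- run_contrasts(m, ann, contrasts = list(T2D_vs_NGT = c("T2D", "NGT")))
  # x = (4,5,6), y = (1,2,3): pooled s2 = 1, t = 3 / sqrt(1 * 2/3)
  t_want <- 3 / sqrt(2 / 3)
  expect_equal(res$t, t_want, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-t_want, df = 4), tolerance = 1e-12)
  expect_equal(res$direction, 1)
})

test_that("t is antisymmetric under group swap; p is invariant", {
  set.seed(51)
  m <- make_lognrq(matrix(rnorm(5 * 10), 5, 10))
  ann <- make_annotations(colnames(m), rep(c("NGT", "T2D"), each = 5))
  fwd <- run_contrasts(m, ann, contrasts = list(a = c("T2D", "NGT")))
  rev <- run_contrasts(m, ann, contrasts = list(a = c("NGT", "T2D")))
  expect_equal(fwd$t, -rev$t, tolerance = 1e-12)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)
})

test_that("significance categories honor the exact star thresholds", {
  expect_equal(significance_category(c(0.05, 0.049999, 0.01, 0.0099,
                                       0.001, 0.0009, 0.5, NA)),
               c("n.s.", "*", "*", "**", "**", "***", "n.s.", NA))
})

test_that("the IGT umbrella pools both subgroups", {
  set.seed(52)
  m <- make_lognrq(matrix(rnorm(3 * 27), 3, 27))
  groups <- rep(c("NGT", "NP_IGT", "P_IGT", "T2D"), c(9, 4, 5, 9))
  ann <- make_annotations(colnames(m), groups)
  res <- run_contrasts(m, ann)
  expect_setequal(unique(res$contrast), names(DEFAULT_CONTRASTS))
  row <- res[res$contrast == "IGT_vs_NGT" & res$assay_id == "miR-1", ]
  expect_equal(row$n1, 9)   # 4 + 5 pooled
  expect_equal(row$n2, 9)
  # manual check of the pooled t
  x <- m[1, groups %in% c("NP_IGT", "P_IGT")]
  y <- m[1, groups == "NGT"]
  expect_equal(row$t, unname(t.test(x, y, var.equal = TRUE)$statistic),
               tolerance = 1e-12)
})

test_that("unknown contrast labels and insufficient data are handled", {
  m <- make_lognrq(matrix(rnorm(12), 2, 6))
  ann <- make_annotations(colnames(m), rep(c("NGT", "T2D"), each = 3))
  expect_error(run_contrasts(m, ann, contrasts = list(x = c("ZZZ", "NGT"))),
               "unknown contrast")
  m2 <- m
  m2[1, 4:6] <- NA  # one group empty for miR-1
  expect_message(
    res <- run_contrasts(m2, ann,
                         contrasts = list(a = c("T2D", "NGT"))),
    "skipped")
  expect_equal(res$assay_id, "miR-2")
})

test_that("signature selection is the union over significant contrasts", {
  res <- tibble::tibble(
    assay_id = c("a", "a", "b", "c"),
    contrast = c("c1", "c2", "c1", "c1"),
    category = c("n.s.", "*", "n.s.", "***"))
  expect_setequal(select_signature(res), c("a", "c"))
  all_ns <- tibble::tibble(assay_id = "a", contrast = "c1", category = "n.s.")
  expect_length(select_signature(all_ns), 0)
  # brute-force scan agreement and monotonicity on random tables
  set.seed(53)
  for (rep in 1:5) {
    tab <- tibble::tibble(
      assay_id = sample(letters[1:10], 30, replace = TRUE),
      contrast = sample(c("c1", "c2", "c3"), 30, replace = TRUE),
      category = sample(c("n.s.", "*", "**", "***"), 30, replace = TRUE,
                        prob = c(0.7, 0.1, 0.1, 0.1)))
    want <- character()
    for (i in seq_len(nrow(tab))) {
      if (tab$category[i] != "n.s.") want <- c(want, tab$assay_id[i])
    }
    expect_setequal(select_signature(tab), unique(want))
    grown <- rbind(tab, tibble::tibble(assay_id = "zz", contrast = "c4",
                                       category = "*"))
    expect_true(all(select_signature(tab) %in% select_signature(grown)))
  }
})

test_that("identical group profiles merge first at height zero", {
  set.seed(54)
  base <- rnorm(6)
  m <- make_lognrq(cbind(base, base, base + 5, base + 9,
                         base, base, base + 5, base + 9))
  colnames(m) <- paste0("S", 1:8)
  ann <- make_annotations(colnames(m),
                          rep(c("NP_IGT", "P_IGT", "NGT", "T2D"), 2))
  dend <- cluster_groups(m, ann, rownames(m))
  expect_setequal(first_merge(dend), c("NP_IGT", "P_IGT"))
  expect_equal(dend$merge_heights[1], 0, tolerance = 1e-12)
  expect_true(all(diff(dend$merge_heights) >= -1e-12))
  expect_match(dend$newick, "NP_IGT")
})

test_that("the dendrogram is invariant to sample order", {
  set.seed(55)
  m <- make_lognrq(matrix(rnorm(5 * 12), 5, 12))
  ann <- make_annotations(colnames(m),
                          rep(c("NGT", "NP_IGT", "P_IGT", "T2D"), each = 3))
  d1 <- cluster_groups(m, ann, rownames(m))
  perm <- sample(12)
  d2 <- cluster_groups(m[, perm], ann[perm, ], rownames(m))
  expect_equal(d1$newick, d2$newick)
})

test_that("clustering validates its inputs", {
  m <- make_lognrq(matrix(rnorm(10), 2, 5))
  ann <- make_annotations(colnames(m), rep("NGT", 5))
  expect_error(cluster_groups(m, ann, character()), "empty")
  expect_error(cluster_groups(m, ann, rownames(m)), "2 groups")
})

test_that("stratified re-analysis contrasts covariate strata", {
  set.seed(56)
  m <- make_lognrq(matrix(rnorm(4 * 20), 4, 20))
  bmi <- runif(20, 20, 35)
  ann <- make_annotations(colnames(m), rep(c("NGT", "T2D"), 10), bmi = bmi)
  res <- stratify_check(m, ann, "bmi", cutpoints = median(bmi))
  expect_equal(unique(res$contrast), "S1_vs_S2")
  # equivalent direct t-test for one assay
  strat <- ifelse(bmi <= median(bmi), "S1", "S2")
  tt <- t.test(m[1, strat == "S1"], m[1, strat == "S2"], var.equal = TRUE)
  expect_equal(res$t[res$assay_id == "miR-1"], unname(tt$statistic),
               tolerance = 1e-12)
  expect_error(stratify_check(m, ann, "waist", cutpoints = 90), "absent")
  expect_error(stratify_check(m, ann, "bmi", cutpoints = 200),
               "fewer than 2 usable strata")
})
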