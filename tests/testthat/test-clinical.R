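test_that("summary-statistics ANOVA reproduces the printed glucose p-value", {
  res <- anova_from_summary(c(81.8, 99.6, 106.8), c(9.1, 8.4, 17.9), c(9, 9, 9))
  expect_equal(round(res$p, 4), 0.0009)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 24)
})

test_that("summary ANOVA equals classical ANOVA on raw data", {
  set.seed(61)
  for (rep in 1:10) {
    ns <- sample(3:12, 3, replace = TRUE)
    y <- unlist(lapply(ns, function(n) rnorm(n, runif(1, 0, 3))))
    g <- factor(rep(seq_along(ns), ns))
    means <- tapply(y, g, mean)
    sds <- tapply(y, g, sd)
    got <- anova_from_summary(means, sds, ns)
    want <- summary(aov(y ~ g))[[1]]
    expect_equal(got$F, want$`F value`[1], tolerance = 1e-10)
    expect_equal(got$p, want$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("summary ANOVA degenerate cases are explicit", {
  flat <- anova_from_summary(c(5, 5, 5), c(1, 2, 1), c(4, 4, 4))
  expect_equal(flat$F, 0)
  expect_equal(flat$p, 1)
  zero <- anova_from_summary(c(1, 2), c(0, 0), c(3, 3))
  expect_true(zero$degenerate)
  expect_equal(zero$p, 0)
  expect_error(anova_from_summary(c(1, 2), c(1, 1), c(1, 3)), "n >= 2")
})

test_that("the 2x2 exact test matches direct hypergeometric summation", {
  tab <- matrix(c(1, 11, 9, 3), 2, 2)  # [[1,9],[11,3]]
  got <- fisher_exact_rxc(tab)
  # enumerate all tables with the observed margins
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  probs <- dhyper(0:min(m, k), m, n, k)
  want <- sum(probs[probs <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("degenerate contingency tables reduce sensibly", {
  # an all-zero column is dropped; a single remaining column is vacuous
  expect_equal(fisher_exact_rxc(matrix(c(3, 4, 0, 0), 2, 2)), 1)
  expect_equal(fisher_exact_rxc(matrix(c(0, 0, 3, 4), 2, 2)), 1)
  expect_error(fisher_exact_rxc(matrix(c(1.5, 2, 3, 4), 2, 2)), "integers")
  # 3x2 runs through the r x c route
  p <- fisher_exact_rxc(matrix(c(4, 5, 2, 5, 4, 7), 3, 2))
  expect_gt(p, 0)
  expect_lte(p, 1)
})

test_that("HOMA conventions differ by the exact glucose unit factor", {
  expect_equal(homa_ir(90, 10, "mgdl_direct"), 40)
  expect_equal(homa_ir(90, 10, "conventional"), 90 * 10 / 405)
  expect_equal(homa_ir(90, 10, "mgdl_direct") /
                 homa_ir(90, 10, "conventional"), 18)
  # linear in each argument
  expect_equal(homa_ir(180, 10), 2 * homa_ir(90, 10))
  expect_equal(homa_ir(90, 30), 3 * homa_ir(90, 10))
  expect_error(homa_ir(0, 10), "positive")
})

test_that("clinical correlation maps find injected couplings and filter rows", {
  set.seed(62)
  n <- 27
  ogtt <- runif(n, 90, 230)
  chol <- runif(n, 150, 250)
  m <- rbind(
    coupled1 = 0.01 * ogtt + 0.001,          # monotone in OGTT
    coupled2 = -0.005 * chol + 0.002 * ogtt, # correlated with both
    lone = rnorm(n)
  )
  colnames(m) <- paste0("S", 1:n)
  ann <- make_annotations(colnames(m),
                          rep(c("NGT", "NP_IGT", "T2D"), each = 9),
                          ogtt_glucose = ogtt, total_cholesterol = chol)
  cm0 <- clinical_correlation_map(m, ann, rownames(m),
                                  c("ogtt_glucose", "total_cholesterol"),
                                  min_significant = 0)
  expect_equal(cm0$r["coupled1", "ogtt_glucose"], 1)
  expect_true(cm0$significant["coupled1", "ogtt_glucose"])
  expect_lt(cm0$r["coupled2", "total_cholesterol"], 0)
  expect_true("lone" %in% cm0$retained)
  # default filter keeps only rows with >= 2 significant correlations
  cm <- clinical_correlation_map(m, ann, rownames(m),
                                 c("ogtt_glucose", "total_cholesterol"))
  expect_false("lone" %in% cm$retained)
  expect_true("coupled2" %in% cm$retained)
  expect_error(clinical_correlation_map(m, ann, rownames(m), "nope"),
               "absent")
})

test_that("coupled1 needs two significant cells to survive the default filter", {
  set.seed(63)
  n <- 20
  ogtt <- runif(n, 90, 230)
  m <- rbind(one = 0.01 * ogtt, noise = rnorm(n))
  colnames(m) <- paste0("S", 1:n)
  ann <- make_annotations(colnames(m), rep(c("NGT", "T2D"), 10),
                          ogtt_glucose = ogtt, hba1c = runif(n, 35, 50))
  cm <- clinical_correlation_map(m, ann, rownames(m),
                                 c("ogtt_glucose", "hba1c"))
  expect_false("one" %in% cm$retained)  # only 1 of 2 significant
})

test_that("the clinical table routes tests by skewness", {
  set.seed(64)
  n <- 30
  groups <- rep(c("NGT", "NP_IGT", "T2D"), each = 10)
  ann <- make_annotations(
    sprintf("S%02d", 1:n), groups,
    normal_shifted = rnorm(n, 50 + 5 * (as.integer(factor(groups))), 2),
    lognormal_var = rlnorm(n, 1, 1.2),
    constant_var = rep(7, n))
  tab <- clinical_table(ann)
  get <- function(v) tab[tab$variable == v, ]
  expect_equal(get("normal_shifted")$test, "anova")
  expect_lt(get("normal_shifted")$p, 0.01)
  expect_equal(get("lognormal_var")$test, "kruskal_wallis")
  expect_equal(get("constant_var")$p, 1)
})

test_that("the clinical table adds a gender row and drops sparse variables", {
  set.seed(65)
  groups <- rep(c("NGT", "NP_IGT", "T2D"), each = 6)
  ann <- make_annotations(sprintf("S%02d", 1:18), groups,
                          bmi = runif(18, 20, 35),
                          sparse = c(runif(5), rep(NA, 13)))
  ann$sex <- rep(c("M", "F"), 9)
  expect_warning(tab <- clinical_table(ann), "sparse")
  expect_true("sex" %in% tab$variable)
  expect_equal(tab$test[tab$variable == "sex"], "fisher_exact")
  expect_false("sparse" %in% tab$variable)
  expect_equal(tab$ngt_n[tab$variable == "bmi"], 6)
})

test_that("reference summaries carry the printed clinical table", {
  tb <- table1_reference()
  expect_equal(nrow(tb), 16)
  expect_equal(tb$printed_p[tb$variable == "fasting_glucose"], 0.0009)
  expect_true(is.na(tb$printed_p[tb$variable == "ogtt_glucose"]))
  expect_equal(tb$printed_p_label[tb$variable == "ogtt_glucose"], "<0.0001")
  expect_true(all(tb$test %in% c("anova", "kruskal_wallis")))
  g <- gender_reference()
  expect_equal(sum(g$pct_males > 0), 3)
})
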