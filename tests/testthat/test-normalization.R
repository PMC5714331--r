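test_that("global mean is the arithmetic mean over the co-expressed set", {
  ct <- make_ct(matrix(c(20, 30, 24, 30), 2, 2))
  gm <- global_mean(ct, c("miR-1", "miR-2"))
  expect_equal(unname(gm), c((20 + 30) / 2, (24 + 30) / 2))
  # single-assay set: the mean is that assay
  expect_equal(unname(global_mean(ct, "miR-1")), c(20, 24))
})

test_that("a 90-assay sample matches brute-force summation", {
  set.seed(5)
  m <- matrix(runif(90 * 4, 20, 35), 90, 4)
  ct <- make_ct(m)
  gm <- global_mean(ct, rownames(ct))
  for (j in 1:4) {
    s <- 0
    for (i in 1:90) s <- s + m[i, j]
    expect_equal(unname(gm[j]), s / 90, tolerance = 1e-12)
  }
})

test_that("undetected cells inside the co-expressed set are an error", {
  ct <- make_ct(matrix(c(20, NA, 24, 30), 2, 2))
  expect_error(global_mean(ct, c("miR-1", "miR-2")), "co-expressed")
})

test_that("NRQ follows 2^(GM - Ct) on the requested log scale", {
  ct <- make_ct(matrix(c(25, 22), 2, 1))
  gm <- c(S1 = 25)
  q <- nrq(ct, gm)
  expect_equal(unclass(q)["miR-1", "S1"], 0)              # Ct = GM -> NRQ 1
  expect_equal(unclass(q)["miR-2", "S1"], log10(8))       # GM 25, Ct 22 -> 8
  expect_equal(10^unclass(q)["miR-2", "S1"], 8, tolerance = 1e-12)
  q2 <- nrq(ct, gm, log_base = 2)
  expect_equal(unclass(q2)["miR-2", "S1"], 3)
})

test_that("log2 NRQs sum to zero over the co-expressed set", {
  set.seed(9)
  for (rep in 1:5) {
    m <- matrix(runif(40 * 6, 18, 36), 40, 6)
    ct <- make_ct(m)
    q <- nrq(ct, coexpressed_set = rownames(ct), log_base = 2)
    expect_lt(max(abs(colSums(unclass(q)))), 1e-9)
  }
})

test_that("NRQ is invariant to per-sample Ct translation", {
  set.seed(10)
  m <- matrix(runif(20 * 5, 20, 34), 20, 5)
  ct <- make_ct(m)
  q1 <- nrq(ct, coexpressed_set = rownames(ct))
  shift <- runif(5, -2, 2)
  q2 <- nrq(make_ct(sweep(m, 2, shift, `+`)),
            coexpressed_set = rownames(ct))
  expect_equal(unclass(q1), unclass(q2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("lower Ct gives strictly higher NRQ at fixed global mean", {
  ct <- make_ct(matrix(seq(30, 20, length.out = 6), 6, 1))
  q <- unclass(nrq(ct, c(S1 = 25)))
  expect_true(all(diff(q[, 1]) > 0))
})

# ---- model-based stability -------------------------------------------------

# straight-from-the-formulas scalar oracle for the grouped decomposition
oracle_stability <- function(x, groups) {
  k <- nrow(x); G <- length(unique(groups)); lev <- unique(groups)
  z <- matrix(NA_real_, k, ncol(x))
  for (j in seq_len(ncol(x))) {
    m_j <- mean(x[, j])
    for (i in seq_len(k)) z[i, j] <- x[i, j] - m_j
  }
  zbar <- s2 <- matrix(NA_real_, k, G)
  n_g <- numeric(G)
  for (g in seq_len(G)) {
    cols <- which(groups == lev[g])
    n_g[g] <- length(cols)
    for (i in seq_len(k)) {
      zbar[i, g] <- mean(z[i, cols])
      s2[i, g] <- var(z[i, cols])
    }
  }
  d <- zbar - rowMeans(zbar)
  sig2 <- matrix(NA_real_, k, G)
  for (g in seq_len(G)) {
    S_hat <- k / (k - 1) * sum(s2[, g])
    for (i in seq_len(k)) {
      sig2[i, g] <- max(0, (s2[i, g] - S_hat / k^2) * k / (k - 2))
    }
  }
  vv <- sweep(sig2, 2, n_g, `/`)
  tau2 <- sum(d^2) / ((G - 1) * (k - 1))
  rho <- numeric(k)
  for (i in seq_len(k)) {
    acc <- 0
    for (g in seq_len(G)) {
      shr <- tau2 / (tau2 + vv[i, g])
      acc <- acc + abs(d[i, g] * shr) + sqrt(vv[i, g] * shr)
    }
    rho[i] <- acc / G
  }
  stats::setNames(rho, rownames(x))
}

test_that("stability values match the straight-from-formula oracle", {
  set.seed(21)
  for (rep in 1:5) {
    k <- sample(3:8, 1)
    n <- 8
    x <- matrix(rnorm(k * n, 25, 1), k, n,
                dimnames = list(paste0("g", 1:k), paste0("S", 1:n)))
    groups <- rep(c("A", "B"), each = n / 2)
    got <- stability_scores(x, groups, include_global_mean = FALSE)
    want <- oracle_stability(x, groups)
    expect_equal(stats::setNames(got$stability_value, got$candidate_id),
                 sort(want), tolerance = 1e-12)
  }
})

test_that("a perfectly stable candidate ranks first", {
  set.seed(22)
  k <- 30
  x <- rbind(target = rep(5, 12),
             matrix(rnorm((k - 1) * 12, 0, 1), k - 1, 12,
                    dimnames = list(paste0("g", 1:(k - 1)), NULL)))
  colnames(x) <- paste0("S", 1:12)
  groups <- rep(c("A", "B", "C"), each = 4)
  res <- stability_scores(x, groups, include_global_mean = FALSE)
  expect_equal(res$candidate_id[1], "target")
})

test_that("the global-mean pseudo-candidate outranks single assays under iid noise", {
  set.seed(23)
  x <- matrix(rnorm(90 * 27, 30, 0.5), 90, 27,
              dimnames = list(paste0("g", 1:90), paste0("S", 1:27)))
  groups <- rep(c("NGT", "IGT", "T2D"), each = 9)
  res <- stability_scores(x, groups, include_global_mean = TRUE)
  expect_equal(res$candidate_id[1], "global_mean")
  expect_lt(res$stability_value[1], min(res$stability_value[-1]))
})

test_that("stability ranking is invariant to group relabeling and gene order", {
  set.seed(24)
  x <- matrix(rnorm(6 * 10, 25, 1), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("S", 1:10)))
  groups <- rep(c("A", "B"), each = 5)
  r1 <- stability_scores(x, groups, include_global_mean = FALSE)
  r2 <- stability_scores(x, ifelse(groups == "A", "Z", "Y"),
                         include_global_mean = FALSE)
  expect_equal(r1$stability_value, r2$stability_value, tolerance = 1e-12)
  perm <- sample(6)
  r3 <- stability_scores(x[perm, ], groups, include_global_mean = FALSE)
  expect_equal(stats::setNames(r1$stability_value, r1$candidate_id),
               stats::setNames(r3$stability_value, r3$candidate_id)[r1$candidate_id],
               tolerance = 1e-12)
})

test_that("stability preconditions are enforced", {
  x <- matrix(rnorm(20), 2, 10)
  expect_error(stability_scores(x, rep(c("A", "B"), 5)), "3 candidate genes")
  x6 <- matrix(rnorm(60), 6, 10,
               dimnames = list(paste0("g", 1:6), paste0("S", 1:10)))
  expect_error(stability_scores(x6, rep("A", 10)), "2 groups")
  expect_error(stability_scores(x6, c(rep("A", 9), "B")), "2 samples per group")
})

test_that("ungrouped stability reduces to corrected overall variation", {
  set.seed(25)
  sds <- c(0.1, 0.5, 1, 2)
  x <- t(sapply(sds, function(s) rnorm(40, 25, s)))
  rownames(x) <- paste0("g", 1:4)
  colnames(x) <- paste0("S", 1:40)
  res <- stability_scores(x, grouped = FALSE, include_global_mean = FALSE)
  # ranking recovers the noise ordering
  expect_equal(res$candidate_id, paste0("g", 1:4))
})
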