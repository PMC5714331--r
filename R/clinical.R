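#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the one-way ANOVA F test exactly from per-group means,
#' standard deviations and sizes: between-group sum of squares
#' `sum(n_i (mean_i - grand_mean)^2)`, within-group sum of squares
#' `sum((n_i - 1) sd_i^2)`, `F = MSb / MSw` on (k − 1, N − k) degrees of
#' freedom. Given exact (unrounded) summaries this is identical to the
#' classical ANOVA on the raw data; applied to a printed table it
#' reproduces the p-values at the table's printed precision.
#'
#' @param means,sds,ns numeric vectors of per-group means, SDs and sizes
#' @return list: `F`, `df1`, `df2`, `p`, `degenerate` (`TRUE` when
#'   `MSw = 0` with `MSb > 0`, reported as p = 0).
#' @examples
#' # fasting glucose, three groups of 9
#' anova_from_summary(c(81.8, 99.6, 106.8), c(9.1, 8.4, 17.9), c(9, 9, 9))
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  stopifnot(length(sds) == k, length(ns) == k)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(ns < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, df1 = df1, df2 = df2, p = 1,
                              degenerate = FALSE))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0, degenerate = TRUE))
  }
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE), degenerate = FALSE)
}

#' Exact test for an r x c contingency table
#'
#' Two-sided conditional exact test: with both margins fixed, the p-value
#' sums the multivariate hypergeometric probabilities of all tables no more
#' probable than the observed one (no mid-p). All-zero rows or columns are
#' dropped before testing; if a single row or column remains the test is
#' vacuous and p = 1.
#'
#' @param counts matrix of non-negative integer counts
#' @return p-value in (0, 1]
#' @export
fisher_exact_rxc <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2) return(1)
  res <- tryCatch(stats::fisher.test(counts, workspace = 2e7),
                  error = function(e) {
                    stop("table too large for exact enumeration: ",
                         conditionMessage(e), call. = FALSE)
                  })
  res$p.value
}

#' HOMA insulin-resistance index
#'
#' Homeostasis-model assessment from fasting glucose and fasting insulin.
#' The `conventional` form divides glucose in mg/dL by 405 (equivalently,
#' glucose in mmol/L by 22.5). The `mgdl_direct` variant, which appears in
#' some clinical reports, applies the 22.5 divisor directly to glucose in
#' mg/dL and therefore runs exactly 18 times higher (18 mg/dL per mmol/L).
#'
#' @param fasting_glucose fasting plasma glucose in mg/dL (> 0)
#' @param insulin fasting insulin in mU/L (> 0)
#' @param convention `"conventional"` or `"mgdl_direct"`
#' @return numeric index, linear in each argument
#' @export
homa_ir <- function(fasting_glucose, insulin,
                    convention = c("conventional", "mgdl_direct")) {
  convention <- match.arg(convention)
  if (any(fasting_glucose <= 0, na.rm = TRUE) ||
      any(insulin <= 0, na.rm = TRUE)) {
    stop("glucose and insulin must be positive", call. = FALSE)
  }
  divisor <- if (convention == "conventional") 405 else 22.5
  fasting_glucose * insulin / divisor
}

#' Bundled clinical reference summaries
#'
#' Printed per-group summary statistics (mean, SD, n = 9 per diagnostic
#' group) of the clinical characterization of the modelled T2D-progression
#' screening cohort, with the test used for each variable and the published
#' p-value. These summaries seed the synthetic clinical covariates and let
#' the ANOVA reconstruction be checked against printed values.
#'
#' @return tibble: `variable`, `ngt_mean`, `ngt_sd`, `igt_mean`, `igt_sd`,
#'   `t2d_mean`, `t2d_sd`, `n_per_group`, `test`, `printed_p` (as printed;
#'   `NA` for the "<0.0001" entry, carried in `printed_p_label`).
#' @export
table1_reference <- function() {
  tb <- tibble::tribble(
    ~variable,          ~ngt_mean, ~ngt_sd, ~igt_mean, ~igt_sd, ~t2d_mean, ~t2d_sd, ~test,            ~printed_p_label,
    "age",                 57.9,     8.9,     62.9,      7.3,     60.2,      8.0,   "anova",          "0.4",
    "weight",              67.2,    12.7,     71.7,     13.0,     78.3,     17.0,   "anova",          "0.3",
    "height",             167.9,    10.5,    166.9,      9.7,    163.3,     11.9,   "anova",          "0.6",
    "bmi",                 23.7,     3.3,     25.6,      3.3,     29.6,      7.8,   "anova",          "0.07",
    "waist",               88.2,    13.0,     96.6,      7.5,    101.0,     11.3,   "anova",          "0.06",
    "fasting_glucose",     81.8,     9.1,     99.6,      8.4,    106.8,     17.9,   "anova",          "0.0009",
    "ogtt_glucose",        94.7,    26.2,    162.8,     21.0,    231.2,     32.6,   "anova",          "<0.0001",
    "hba1c",               36.8,     2.2,     44.6,      3.4,     46.4,      6.3,   "anova",          "0.0002",
    "insulin",             11.6,    12.3,     31.3,     48.5,     18.8,     11.9,   "kruskal_wallis", "0.03",
    "homa",                 2.6,     3.2,      7.7,     11.8,      5.1,      3.6,   "kruskal_wallis", "0.02",
    "triglycerides",      103.3,    58.0,    158.7,     69.9,    116.1,     61.7,   "anova",          "0.2",
    "total_cholesterol",  196.4,    26.0,    218.7,     23.2,    199.0,     30.5,   "anova",          "0.2",
    "ldl_cholesterol",    116.2,    18.5,    132.7,     28.0,    121.9,     30.3,   "anova",          "0.4",
    "hdl_cholesterol",     59.6,    14.2,     54.2,     17.9,     53.9,     16.5,   "anova",          "0.7",
    "microalbuminuria",     8.0,     7.1,     76.1,    150.4,      7.8,      5.0,   "kruskal_wallis", "0.07",
    "endothelial_function", 2.2,     0.5,      2.4,      0.9,      2.5,      0.7,   "anova",          "0.7"
  )
  tb$n_per_group <- 9L
  tb$printed_p <- suppressWarnings(as.numeric(tb$printed_p_label))
  tb
}

#' Reference gender split
#'
#' Printed percentage of males per diagnostic group (n = 9 each) with the
#' published exact-test p-value.
#' @return list: `pct_males`, `n_per_group`, `printed_p`
#' @export
gender_reference <- function() {
  list(pct_males = c(NGT = 44, IGT = 56, T2D = 22), n_per_group = 9L,
       printed_p = 0.3)
}

#' miRNA-by-clinical correlation map
#'
#' Spearman correlation of every signature miRNA (log NRQ) with every
#' requested clinical variable, over the samples carrying both values. By
#' default only miRNAs significantly correlated (p <= `alpha`) with at
#' least `min_significant` variables are retained, mirroring the usual
#' reporting filter for such maps.
#'
#' @param lognrq an [nrq()] matrix
#' @param annotations sample annotations with the clinical columns
#' @param signature assay ids (rows of the map)
#' @param variables clinical column names (columns of the map)
#' @param alpha significance level for the mask (default 0.05, inclusive)
#' @param min_significant row filter threshold; 0 disables the filter
#' @return list of class `clinical_correlation_map`: matrices `r`, `p`,
#'   `significant`, plus `retained` (assay ids passing the filter; the
#'   matrices are restricted to them).
#' @export
clinical_correlation_map <- function(lognrq, annotations, signature, variables,
                                     alpha = 0.05, min_significant = 2) {
  stopifnot(length(signature) > 0, length(variables) > 0)
  absent <- setdiff(variables, names(annotations))
  if (length(absent)) stop("clinical variable(s) absent: ",
                           paste(absent, collapse = ", "), call. = FALSE)
  m <- as.matrix(lognrq)[signature, , drop = FALSE]
  ann <- annotations[match(colnames(m), annotations$sample_id), ]
  r <- matrix(NA_real_, length(signature), length(variables),
              dimnames = list(signature, variables))
  p <- r
  for (a in signature) for (v in variables) {
    s <- spearman_cor(m[a, ], ann[[v]])
    r[a, v] <- s$r
    p[a, v] <- s$p
  }
  sig <- !is.na(p) & p <= alpha
  retained <- signature[rowSums(sig) >= min_significant]
  structure(list(r = r[retained, , drop = FALSE],
                 p = p[retained, , drop = FALSE],
                 significant = sig[retained, , drop = FALSE],
                 retained = retained, alpha = alpha),
            class = "clinical_correlation_map")
}

#' @export
print.clinical_correlation_map <- function(x, ...) {
  cat(sprintf("<clinical_correlation_map> %d miRNAs x %d variables (%d significant cells at p <= %g)\n",
              nrow(x$r), ncol(x$r), sum(x$significant), x$alpha))
  invisible(x)
}

moment_skewness <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 3 || stats::sd(v) == 0) return(0)
  m <- mean(v)
  mean((v - m)^3) / (mean((v - m)^2))^1.5
}

#' Clinical group-comparison table
#'
#' Per clinical variable: per-diagnostic-group mean, SD and n, plus a
#' group-comparison p-value. The test is chosen by a skewness rule:
#' Kruskal–Wallis when any group's moment skewness exceeds
#' `skew_threshold` in absolute value (heavy-tailed clinical markers such
#' as insulin), one-way ANOVA otherwise. Variables missing in more than
#' half the samples are excluded with a warning. When a `sex` column is
#' present, a gender row is added with an exact r x c contingency test.
#'
#' @param annotations sample annotations (clinical columns numeric)
#' @param variables columns to summarize; default every numeric column
#' @param skew_threshold absolute skewness routing threshold (default 1)
#' @return tibble: `variable`, per-group `mean`/`sd`/`n` columns, `test`,
#'   `p`.
#' @export
clinical_table <- function(annotations, variables = NULL, skew_threshold = 1) {
  ann <- annotations
  grp <- diagnostic_group(ann$group)
  lev <- c("NGT", "IGT", "T2D")
  lev <- lev[lev %in% grp]
  if (is.null(variables)) {
    variables <- names(ann)[vapply(ann, is.numeric, TRUE)]
  }
  rows <- list()
  for (v in variables) {
    val <- ann[[v]]
    if (mean(is.na(val)) > 0.5) {
      warning("variable ", v, " missing in >50% of samples; excluded",
              call. = FALSE)
      next
    }
    stats_g <- lapply(lev, function(g) {
      x <- val[grp == g & !is.na(val)]
      c(mean = mean(x), sd = stats::sd(x), n = length(x))
    })
    skewed <- any(vapply(lev, function(g)
      abs(moment_skewness(val[grp == g])) > skew_threshold, TRUE))
    ok <- !is.na(val)
    if (length(unique(val[ok])) == 1) {
      test <- if (skewed) "kruskal_wallis" else "anova"
      pv <- 1
    } else if (skewed) {
      test <- "kruskal_wallis"
      pv <- kruskal_wallis(val[ok], grp[ok])$p
    } else {
      test <- "anova"
      sm <- vapply(stats_g, identity, numeric(3))
      pv <- anova_from_summary(sm["mean", ], sm["sd", ], sm["n", ])$p
    }
    row <- tibble::tibble(variable = v)
    for (i in seq_along(lev)) {
      row[[paste0(tolower(lev[i]), "_mean")]] <- stats_g[[i]][["mean"]]
      row[[paste0(tolower(lev[i]), "_sd")]] <- stats_g[[i]][["sd"]]
      row[[paste0(tolower(lev[i]), "_n")]] <- stats_g[[i]][["n"]]
    }
    row$test <- test
    row$p <- pv
    rows[[v]] <- row
  }
  out <- do.call(rbind, rows)
  if ("sex" %in% names(ann)) {
    counts <- table(factor(grp, levels = lev), factor(ann$sex))
    gender <- tibble::tibble(variable = "sex")
    for (g in lev) {
      gender[[paste0(tolower(g), "_mean")]] <- NA_real_
      gender[[paste0(tolower(g), "_sd")]] <- NA_real_
      gender[[paste0(tolower(g), "_n")]] <- sum(grp == g)
    }
    gender$test <- "fisher_exact"
    gender$p <- fisher_exact_rxc(unclass(counts))
    out <- rbind(out, gender)
  }
  out
}
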