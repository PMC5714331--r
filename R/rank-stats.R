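#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value from
#' the large-sample t approximation (stable in the presence of ties, which
#' are ubiquitous in Ct data printed at fixed precision). Pairs with a
#' missing value in either vector are dropped.
#'
#' @param x,y numeric vectors of equal length
#' @return list: `r`, `p`, `n` (pairs used), and `constant` — `TRUE` when one
#'   input is constant, in which case `r` and `p` are `NA` (flagged, never
#'   silently zero).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(r = NA_real_, p = NA_real_, n = n, constant = TRUE))
  }
  ht <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(r = unname(ht$estimate), p = ht$p.value, n = n, constant = FALSE)
}

#' Kruskal–Wallis rank test
#'
#' Tie-corrected H with a chi-squared p on k − 1 degrees of freedom. The
#' degenerate all-identical case returns H = 0, p = 1 rather than an error.
#'
#' @param values numeric vector
#' @param groups group label per value (2 or more groups)
#' @return list: `H`, `p`, `df`
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(as.character(groups)[keep])
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(unique(values)) == 1) {
    return(list(H = 0, p = 1, df = nlevels(groups) - 1L))
  }
  ht <- stats::kruskal.test(values, groups)
  list(H = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Dunn's post-hoc comparisons
#'
#' Pairwise z statistics from pooled rank means after a Kruskal–Wallis test,
#' with tie-corrected variance, for a requested family of comparisons
#' against a reference group. p-values are two-sided normal and adjusted
#' over the requested family only.
#'
#' @param values numeric vector
#' @param groups group label per value
#' @param comparisons two-column data frame (or list of length-2 vectors)
#'   naming `group` and `reference` pairs; default all groups vs `reference`.
#' @param reference reference group used when `comparisons` is `NULL`.
#' @param method multiplicity adjustment over the family: `"bonferroni"`
#'   (classical Dunn), `"holm"`, `"sidak"`, or `"none"`.
#' @return tibble: `group`, `reference`, `z`, `p`, `p_adjusted`
#' @export
dunn_posthoc <- function(values, groups, comparisons = NULL, reference = NULL,
                         method = c("bonferroni", "holm", "sidak", "none")) {
  method <- match.arg(method)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  lev <- unique(groups)
  if (is.null(comparisons)) {
    if (is.null(reference)) stop("give either `comparisons` or `reference`",
                                 call. = FALSE)
    comparisons <- data.frame(group = setdiff(lev, reference),
                              reference = reference)
  } else if (!is.data.frame(comparisons)) {
    comparisons <- as.data.frame(do.call(rbind, comparisons),
                                 stringsAsFactors = FALSE)
    names(comparisons) <- c("group", "reference")
  }
  unknown <- setdiff(unique(unlist(comparisons)), lev)
  if (length(unknown)) stop("unknown group name(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  z <- mapply(function(a, b) {
    (rbar[[a]] - rbar[[b]]) / sqrt(sigma2 * (1 / ng[[a]] + 1 / ng[[b]]))
  }, comparisons$group, comparisons$reference)
  z[!is.finite(z)] <- 0  # identical constant data
  p <- 2 * stats::pnorm(-abs(z))
  m <- nrow(comparisons)
  p_adj <- switch(method,
                  bonferroni = pmin(1, p * m),
                  holm = stats::p.adjust(p, "holm"),
                  sidak = 1 - (1 - p)^m,
                  none = p)
  tibble::tibble(group = comparisons$group, reference = comparisons$reference,
                 z = unname(z), p = unname(p), p_adjusted = unname(p_adj))
}
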