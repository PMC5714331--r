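#' Per-sample global mean Ct
#'
#' Arithmetic mean Ct over the co-expressed assays (those detected in every
#' sample), the endogenous normalizer for panel-wide relative
#' quantification.
#'
#' @param ct a [ct_matrix()]
#' @param coexpressed_set assay ids detected in every sample (see
#'   [detection_summary()])
#' @return named numeric vector, one mean Ct per sample (cycles).
#' @export
global_mean <- function(ct, coexpressed_set) {
  stopifnot(inherits(ct, "ct_matrix"))
  missing <- setdiff(coexpressed_set, rownames(ct))
  if (length(missing)) stop("assay(s) not in matrix: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  sub <- unclass(ct)[coexpressed_set, , drop = FALSE]
  if (anyNA(sub)) {
    bad <- which(colSums(is.na(sub)) > 0)
    stop("undetected cell(s) inside the co-expressed set (sample ",
         paste(colnames(sub)[bad], collapse = ", "),
         "); the set must be fully detected", call. = FALSE)
  }
  colMeans(sub)
}

#' Normalized relative quantities
#'
#' NRQ(a, s) = 2^(GM_s − Ct_{a,s}), the quantity of assay `a` in sample `s`
#' relative to the sample's global mean, stored on a log scale. The exponent
#' base is always 2 (one PCR cycle = one doubling); `log_base` only controls
#' the reporting scale (log10 by default, as in the figure conventions of
#' this analysis family).
#'
#' Algebraic consequence: over the co-expressed set the per-sample mean of
#' (GM − Ct) is zero, so log2 NRQs sum to zero and the NRQ product is 1.
#'
#' @param ct a [ct_matrix()]
#' @param gm per-sample global mean; computed from `coexpressed_set` when
#'   omitted.
#' @param coexpressed_set assay ids defining the normalizer (needed when
#'   `gm` is missing).
#' @param log_base base for the stored logarithm (10 or 2).
#' @return matrix of class `nrq_matrix` (assays x samples, log-scale NRQ,
#'   `NA` where undetected) with attributes `log_base`, `global_mean`, and
#'   `coexpressed_set`.
#' @export
nrq <- function(ct, gm = NULL, coexpressed_set = NULL, log_base = 10) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (is.null(gm)) {
    if (is.null(coexpressed_set)) stop("need `gm` or `coexpressed_set`",
                                       call. = FALSE)
    gm <- global_mean(ct, coexpressed_set)
  }
  if (!all(colnames(ct) %in% names(gm))) {
    stop("global mean missing for some samples", call. = FALSE)
  }
  gm <- gm[colnames(ct)]
  m <- sweep(unclass(ct), 2, gm, function(ct_val, g) (g - ct_val))
  m <- m * log(2) / log(log_base)
  structure(m, class = "nrq_matrix", log_base = log_base,
            global_mean = gm, coexpressed_set = coexpressed_set)
}

#' @export
print.nrq_matrix <- function(x, ...) {
  cat(sprintf("<nrq_matrix> %d assays x %d samples, log%g scale\n",
              nrow(x), ncol(x), attr(x, "log_base")))
  invisible(x)
}

# Core model-based stability decomposition on log2-scale quantities.
# x: genes x samples, groups: factor. Returns per-gene/group intragroup
# variance estimates and intergroup deviations plus the combined score.
# Independent scalar oracle lives in the test suite.
normfinder_decompose <- function(z, groups, k) {
  G <- nlevels(groups)
  genes <- rownames(z)
  s2 <- matrix(NA_real_, nrow(z), G, dimnames = list(genes, levels(groups)))
  d <- s2
  n_g <- integer(G)
  for (g in seq_len(G)) {
    cols <- which(groups == levels(groups)[g])
    n_g[g] <- length(cols)
    zg <- z[, cols, drop = FALSE]
    d[, g] <- rowMeans(zg)
    s2[, g] <- apply(zg, 1, stats::var)
  }
  d <- d - rowMeans(d)  # gene-by-group interaction: remove gene main effect
  list(s2 = s2, d = d, n_g = n_g)
}

#' Model-based normalizer stability
#'
#' Ranks candidate normalizers by a variance-decomposition stability value
#' on log2-scale quantities: for each candidate, its expression relative to
#' the candidate-set average is decomposed into an intragroup variance and a
#' systematic intergroup deviation, and the two are combined (an
#' empirical-Bayes shrinkage of the group deviations plus their posterior
#' spread) into a single score — lower is more stable. Negative intermediate
#' variance estimates are truncated at zero.
#'
#' The per-sample mean over the candidate set can be scored as the
#' pseudo-candidate `"global_mean"`. Its intergroup deviation relative to
#' the set average is identically zero by construction (relative
#' quantification cannot assess the normalizer's own bias), so its score
#' reflects the estimated sampling variance of the set average,
#' `sum(variances)/k^2` per group; the candidate-set average used by the
#' model always excludes the pseudo-candidate.
#'
#' @param x genes x samples matrix of log2-scale quantities (e.g. −Ct or
#'   log2 NRQ; any per-sample constant offset cancels).
#' @param groups group label per sample (2+ groups, 2+ samples each) when
#'   `grouped = TRUE`.
#' @param include_global_mean add the pseudo-candidate row. Default `TRUE`.
#' @param grouped `FALSE` scores candidates by overall corrected variance
#'   without a group structure.
#' @return tibble sorted by ascending `stability_value`: `candidate_id`,
#'   `stability_value`, `rank`; per-group intragroup variances and
#'   intergroup deviations are attached as attributes `intragroup_variance`
#'   and `intergroup_bias`.
#' @export
stability_scores <- function(x, groups = NULL, include_global_mean = TRUE,
                             grouped = TRUE) {
  x <- as.matrix(x)
  k <- nrow(x)
  if (k < 3) stop("need at least 3 candidate genes", call. = FALSE)
  if (anyNA(x)) stop("stability candidates must have complete data", call. = FALSE)
  sample_mean <- colMeans(x)
  z <- sweep(x, 2, sample_mean)
  if (include_global_mean) {
    z <- rbind(z, global_mean = 0)  # the set average minus itself
  }
  if (grouped) {
    if (is.null(groups)) stop("grouped mode needs `groups`", call. = FALSE)
    groups <- factor(as.character(groups))
    if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
    if (any(table(groups) < 2)) stop("need at least 2 samples per group",
                                     call. = FALSE)
    dec <- normfinder_decompose(z, groups, k)
    G <- nlevels(groups)
    # contamination-corrected intragroup variances (real genes)
    real <- seq_len(k)
    sig2 <- dec$s2
    for (g in seq_len(G)) {
      S_hat <- k / (k - 1) * sum(dec$s2[real, g])
      sig2[real, g] <- pmax(0, (dec$s2[real, g] - S_hat / k^2) * k / (k - 2))
      if (include_global_mean) sig2["global_mean", g] <- S_hat / k^2
    }
    d <- dec$d
    if (include_global_mean) d["global_mean", ] <- 0
    vv <- sweep(sig2, 2, dec$n_g, `/`)
    # conservative (non-deflated) estimate of the intergroup variance; keeps
    # the score defined and variance-sensitive when true group effects vanish
    tau2 <- sum(d[real, , drop = FALSE]^2) / ((G - 1) * (k - 1))
    shrink <- tau2 / (tau2 + vv)
    shrink[!is.finite(shrink)] <- 0   # tau2 = 0 and vv = 0
    d_new <- d * shrink
    var_new <- vv * shrink
    rho <- rowMeans(abs(d_new) + sqrt(var_new))
    intra <- sig2
    bias <- d
  } else {
    real <- seq_len(k)
    s2 <- apply(z, 1, stats::var)
    S_hat <- k / (k - 1) * sum(s2[real])
    sig2 <- pmax((s2[real] - S_hat / k^2) * k / (k - 2), 0)
    rho <- sqrt(sig2)
    if (include_global_mean) rho <- c(rho, global_mean = sqrt(S_hat / k^2))
    intra <- cbind(all = c(sig2, if (include_global_mean)
      c(global_mean = S_hat / k^2)))
    bias <- NULL
  }
  ord <- order(rho)
  out <- tibble::tibble(candidate_id = names(rho)[ord],
                        stability_value = unname(rho)[ord],
                        rank = seq_along(rho))
  attr(out, "intragroup_variance") <- intra
  attr(out, "intergroup_bias") <- bias
  out
}
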