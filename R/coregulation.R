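#' Global-quantity trend versus clinical variables
#'
#' Correlates the per-sample miRNA global quantity — the reversed (negated)
#' global mean Ct, so that higher means more miRNA — with clinical variables
#' (2-hour OGTT glucose and HbA1c by default) across all samples, by
#' Spearman rank correlation. Samples missing a clinical value are dropped
#' with a notice.
#'
#' @param ct a [ct_matrix()]
#' @param annotations sample annotations with the clinical columns
#' @param coexpressed_set assays defining the global mean
#' @param clinical_vars annotation column names to correlate against
#' @return tibble: `variable`, `n`, `r`, `p`
#' @export
group_quantity_trend <- function(ct, annotations, coexpressed_set,
                                 clinical_vars = c("ogtt_glucose", "hba1c")) {
  gm <- global_mean(ct, coexpressed_set)
  ann <- annotations[match(colnames(ct), annotations$sample_id), ]
  out <- lapply(clinical_vars, function(v) {
    if (!v %in% names(ann)) stop("clinical variable absent: ", v, call. = FALSE)
    val <- ann[[v]]
    if (anyNA(val)) message(sum(is.na(val)), " sample(s) missing ", v,
                            "; dropped")
    ok <- !is.na(val)
    s <- spearman_cor(-gm[ok], val[ok])
    tibble::tibble(variable = v, n = s$n, r = s$r, p = s$p)
  })
  do.call(rbind, out)
}

#' Per-group co-regulation profiles
#'
#' For each diagnostic group separately, computes the Spearman correlation
#' of every co-expressed miRNA with the group's per-sample global mean, the
#' group average of those correlations, and the full miRNA-by-miRNA
#' Spearman matrix. The per-miRNA correlation distributions are then
#' compared across groups by Kruskal–Wallis with Dunn's comparisons against
#' `reference_group` — the diagnostic for a group-specific loss of
#' quantitative co-regulation.
#'
#' Correlations are computed on raw Ct values within each group; because
#' the statistic is rank-based, using reversed Ct or log NRQ changes only
#' the sign convention.
#'
#' @param ct a [ct_matrix()]
#' @param annotations sample annotations
#' @param coexpressed_set assay ids detected in all samples
#' @param reference_group Dunn reference (default `"IGT"`)
#' @param group_by `"diagnostic"` (NGT/IGT/T2D) or `"progression"`
#'   (four-level split)
#' @param min_n groups with fewer samples are skipped with a warning
#' @return list with `profiles` — per group a list holding `group`,
#'   `per_mirna_r` (named vector), `mean_r`, `pairwise_r` (symmetric matrix,
#'   unit diagonal) — and `test`, the Kruskal–Wallis result plus the Dunn
#'   table on the per-miRNA correlations.
#' @export
correlation_profiles <- function(ct, annotations, coexpressed_set,
                                 reference_group = "IGT",
                                 group_by = c("diagnostic", "progression"),
                                 min_n = 3) {
  group_by <- match.arg(group_by)
  stopifnot(inherits(ct, "ct_matrix"))
  ann <- annotations[match(colnames(ct), annotations$sample_id), ]
  grp <- if (group_by == "diagnostic") diagnostic_group(ann$group) else ann$group
  profiles <- list()
  for (g in unique(grp)) {
    cols <- which(grp == g)
    if (length(cols) < min_n) {
      warning("group ", g, " has fewer than ", min_n, " samples; skipped",
              call. = FALSE)
      next
    }
    sub <- unclass(ct)[coexpressed_set, cols, drop = FALSE]
    gm <- colMeans(sub)
    per_r <- apply(sub, 1, function(v) {
      s <- spearman_cor(v, gm)
      s$r
    })
    pw <- stats::cor(t(sub), method = "spearman")
    diag(pw) <- 1
    profiles[[g]] <- list(group = g, per_mirna_r = per_r,
                          mean_r = mean(per_r, na.rm = TRUE), pairwise_r = pw)
  }
  test <- NULL
  if (length(profiles) >= 2) {
    rv <- unlist(lapply(profiles, `[[`, "per_mirna_r"))
    gv <- rep(names(profiles), vapply(profiles, function(p)
      length(p$per_mirna_r), 1L))
    kw <- kruskal_wallis(rv, gv)
    dunn <- if (reference_group %in% names(profiles)) {
      dunn_posthoc(rv, gv, reference = reference_group)
    }
    test <- list(kruskal_wallis = kw, dunn = dunn)
  }
  list(profiles = profiles, test = test)
}

#' Local-versus-global coupling slope
#'
#' Within each diagnostic group, ordinary least squares of one assay's raw
#' Ct on the per-sample global-mean Ct. A slope of 1 means the assay tracks
#' the global miRNA quantity one-to-one; attenuation of the slope across
#' progression groups indicates the assay's quantity decoupling from the
#' global signal.
#'
#' @param ct a [ct_matrix()]
#' @param assay_id assay to regress
#' @param annotations sample annotations
#' @param coexpressed_set assays defining the global mean
#' @param min_n minimum detected samples per group for a reported slope
#' @return tibble: `assay_id`, `group`, `slope`, `intercept`, `n`,
#'   `degenerate` (`TRUE` when the global mean is constant within the
#'   group, leaving the slope undefined).
#' @export
local_vs_global_slope <- function(ct, assay_id, annotations, coexpressed_set,
                                  min_n = 3) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!assay_id %in% rownames(ct)) stop("assay not in panel: ", assay_id,
                                        call. = FALSE)
  gm <- global_mean(ct, coexpressed_set)
  ann <- annotations[match(colnames(ct), annotations$sample_id), ]
  grp <- diagnostic_group(ann$group)
  rows <- list()
  for (g in unique(grp)) {
    cols <- which(grp == g)
    y <- unclass(ct)[assay_id, cols]
    x <- gm[cols]
    ok <- !is.na(y)
    y <- y[ok]; x <- x[ok]
    if (length(y) < min_n) next
    if (stats::var(x) == 0) {
      rows[[g]] <- tibble::tibble(assay_id = assay_id, group = g,
                                  slope = NA_real_, intercept = NA_real_,
                                  n = length(y), degenerate = TRUE)
      next
    }
    b <- stats::cov(x, y) / stats::var(x)
    a <- mean(y) - b * mean(x)
    rows[[g]] <- tibble::tibble(assay_id = assay_id, group = g, slope = b,
                                intercept = a, n = length(y),
                                degenerate = FALSE)
  }
  do.call(rbind, rows)
}
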