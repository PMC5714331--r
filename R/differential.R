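#' Default contrast lattice
#'
#' The five group comparisons of the progression design: pooled IGT, its
#' two subgroups and T2D each against NGT, plus non-progressors against
#' progressors. `IGT` pools the `NP_IGT` and `P_IGT` samples.
#' @export
DEFAULT_CONTRASTS <- list(
  IGT_vs_NGT    = c("IGT", "NGT"),
  NP_IGT_vs_NGT = c("NP_IGT", "NGT"),
  P_IGT_vs_NGT  = c("P_IGT", "NGT"),
  T2D_vs_NGT    = c("T2D", "NGT"),
  NP_vs_P_IGT   = c("NP_IGT", "P_IGT")
)

#' Significance category from a p-value
#'
#' `n.s.` for p >= 0.05, `*` below 0.05, `**` below 0.01, `***` below
#' 0.001 — the star convention of the contrast table.
#' @param p numeric vector of p-values
#' @return character vector of categories
#' @export
significance_category <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "n.s."))))
}

resolve_group <- function(label, lookup) {
  if (label == "IGT") which(lookup %in% c("NP_IGT", "P_IGT"))
  else which(lookup == label)
}

#' Run the group-contrast lattice
#'
#' Per assay and contrast, a two-sided unpaired t test on log-NRQ values
#' (pooled-variance Student by default; `var_equal = FALSE` for Welch),
#' with the star significance category and the direction of the mean
#' difference (first-named group minus reference). Assays with fewer than
#' 2 defined values in either group are skipped with a notice. No
#' correction across assays is applied by default, matching the raw
#' p < 0.05 convention of this analysis family; `p_adjust = "BH"` adds a
#' false-discovery-rate column for modern use.
#'
#' @param lognrq an [nrq()] matrix (or any assay x sample value matrix)
#' @param annotations sample annotations (column `group`), or supply
#'   `group_lookup` directly
#' @param contrasts named list, each element `c(group, reference)`; group
#'   labels may be the four levels or the `IGT` umbrella. Default
#'   [DEFAULT_CONTRASTS].
#' @param var_equal pooled-variance Student t (default) or Welch
#' @param p_adjust `"none"` (default) or a [stats::p.adjust] method applied
#'   per contrast across assays, reported as `p_adj`.
#' @param group_lookup optional character vector of group labels aligned to
#'   `colnames(lognrq)`, overriding `annotations` (used for stratified
#'   re-analysis).
#' @return tibble: `assay_id`, `contrast`, `n1`, `n2`, `t`, `p`,
#'   `category`, `direction`.
#' @export
run_contrasts <- function(lognrq, annotations = NULL,
                          contrasts = DEFAULT_CONTRASTS, var_equal = TRUE,
                          p_adjust = "none", group_lookup = NULL) {
  m <- as.matrix(lognrq)
  if (is.null(group_lookup)) {
    ann <- annotations[match(colnames(m), annotations$sample_id), ]
    group_lookup <- ann$group
  }
  if (is.null(names(contrasts)) || any(names(contrasts) == "")) {
    stop("contrasts must be a named list", call. = FALSE)
  }
  known <- c(GROUP_LEVELS, "IGT", unique(group_lookup))
  rows <- vector("list", length(contrasts))
  skipped <- 0L
  for (ci in seq_along(contrasts)) {
    pair <- contrasts[[ci]]
    if (length(pair) != 2 || !all(pair %in% known)) {
      stop("unknown contrast label or groups: ", names(contrasts)[ci],
           call. = FALSE)
    }
    i1 <- resolve_group(pair[1], group_lookup)
    i2 <- resolve_group(pair[2], group_lookup)
    res <- lapply(rownames(m), function(a) {
      x <- m[a, i1]; y <- m[a, i2]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2 || length(y) < 2) {
        skipped <<- skipped + 1L
        return(NULL)
      }
      if (stats::var(x) == 0 && stats::var(y) == 0) {
        # degenerate: no residual variance
        tt <- if (mean(x) == mean(y)) list(statistic = c(t = 0), p.value = 1)
              else list(statistic = c(t = sign(mean(x) - mean(y)) * Inf),
                        p.value = 0)
      } else {
        tt <- stats::t.test(x, y, var.equal = var_equal)
      }
      tibble::tibble(assay_id = a, contrast = names(contrasts)[ci],
                     n1 = length(x), n2 = length(y),
                     t = unname(tt$statistic), p = tt$p.value,
                     direction = sign(mean(x) - mean(y)))
    })
    rows[[ci]] <- do.call(rbind, res)
  }
  if (skipped) message(skipped, " assay/contrast combination(s) skipped: ",
                       "fewer than 2 defined values in a group")
  out <- do.call(rbind, rows)
  out$category <- significance_category(out$p)
  if (p_adjust != "none") {
    out$p_adj <- stats::ave(out$p, out$contrast,
                            FUN = function(p) stats::p.adjust(p, p_adjust))
  }
  out[, c("assay_id", "contrast", "n1", "n2", "t", "p", "category",
          "direction", if (p_adjust != "none") "p_adj")]
}

#' Differentially expressed signature
#'
#' Union of assays reaching significance (category other than `n.s.`) in at
#' least one contrast.
#'
#' @param results output of [run_contrasts()]
#' @return character vector of assay ids
#' @export
select_signature <- function(results) {
  stopifnot(nrow(results) > 0)
  unique(results$assay_id[results$category != "n.s." & !is.na(results$category)])
}

#' Hierarchical clustering of group profiles
#'
#' Agglomerative clustering of the per-group mean log-NRQ vectors over the
#' signature assays — four leaves for the four progression groups. Which
#' groups merge first shows which expression profiles resemble each other.
#'
#' @param lognrq an [nrq()] matrix
#' @param annotations sample annotations
#' @param signature assay ids to use (from [select_signature()])
#' @param linkage [stats::hclust] agglomeration method (default
#'   `"average"`)
#' @param metric [stats::dist] method (default `"euclidean"`)
#' @return object of class `group_dendrogram`: list with `hclust`, `leaves`,
#'   `merge_heights`, `linkage`, `metric`, and `newick` (string form).
#' @export
cluster_groups <- function(lognrq, annotations, signature,
                           linkage = "average", metric = "euclidean") {
  if (!length(signature)) stop("signature is empty", call. = FALSE)
  m <- as.matrix(lognrq)[signature, , drop = FALSE]
  ann <- annotations[match(colnames(m), annotations$sample_id), ]
  groups <- sort(unique(ann$group))
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  prof <- vapply(groups, function(g) {
    rowMeans(m[, ann$group == g, drop = FALSE], na.rm = TRUE)
  }, numeric(length(signature)))
  hc <- stats::hclust(stats::dist(t(prof), method = metric), method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, leaves = hc$labels,
                 merge_heights = hc$height, linkage = linkage,
                 metric = metric,
                 newick = ape::write.tree(phy)),
            class = "group_dendrogram")
}

#' @export
print.group_dendrogram <- function(x, ...) {
  cat("<group_dendrogram>", x$newick, "\n")
  invisible(x)
}

#' First merge of a group dendrogram
#'
#' Convenience accessor: the pair of leaves joined at the lowest height.
#' @param dend a [cluster_groups()] result
#' @return character vector of the two leaf labels merged first
#' @export
first_merge <- function(dend) {
  hc <- dend$hclust
  pair <- hc$merge[1, ]
  hc$labels[-pair]
}

#' Stratified re-analysis
#'
#' Re-runs the contrast machinery with groups defined by strata of a
#' clinical covariate (BMI by default) instead of the diagnostic groups —
#' the control showing whether the signature tracks glucose metabolism or
#' the covariate. All pairwise stratum contrasts are tested.
#'
#' @param lognrq an [nrq()] matrix
#' @param annotations sample annotations holding `variable`
#' @param variable annotation column to stratify on
#' @param cutpoints boundaries passed to [cut()] (inner cutpoints;
#'   -Inf/Inf added)
#' @param min_n strata smaller than this are dropped with a notice
#' @inheritParams run_contrasts
#' @return as [run_contrasts()], with contrasts named `<a>_vs_<b>` over
#'   stratum labels `S1`, `S2`, ...
#' @export
stratify_check <- function(lognrq, annotations, variable = "bmi", cutpoints,
                           min_n = 2, var_equal = TRUE) {
  if (!variable %in% names(annotations)) {
    stop("stratification variable absent: ", variable, call. = FALSE)
  }
  m <- as.matrix(lognrq)
  ann <- annotations[match(colnames(m), annotations$sample_id), ]
  val <- ann[[variable]]
  strat <- cut(val, breaks = c(-Inf, cutpoints, Inf),
               labels = paste0("S", seq_len(length(cutpoints) + 1)))
  strat <- as.character(strat)
  sizes <- table(strat)
  small <- names(sizes)[sizes < min_n]
  if (length(small)) {
    message("stratum(a) below minimum size dropped: ",
            paste(small, collapse = ", "))
    strat[strat %in% small] <- NA
  }
  lev <- sort(unique(strat[!is.na(strat)]))
  if (length(lev) < 2) stop("fewer than 2 usable strata; nothing to contrast",
                            call. = FALSE)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  contrasts <- stats::setNames(pairs,
                               vapply(pairs, function(p)
                                 paste0(p[1], "_vs_", p[2]), ""))
  run_contrasts(m, contrasts = contrasts, var_equal = var_equal,
                group_lookup = strat)
}
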