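#' Assay-level quality control
#'
#' Applies the three panel QC filters: assays whose melting curve shows
#' several (or out-of-spec) melting points, assays with amplification
#' efficiency below `min_efficiency`, and reactions whose Ct falls within
#' `margin` cycles of the assay's negative control. Flagged data are set to
#' the undetected state and logged with exactly one primary reason each.
#'
#' Melting and efficiency failures are properties of the assay and always
#' remove the whole panel row. The negative-control rule is applied per cell
#' by default (`scope = "cell"`); `scope = "assay"` removes the whole row as
#' soon as one reaction violates the margin, the stricter reading.
#' Assays whose negative control did not amplify pass the margin rule.
#'
#' @param ct a [ct_matrix()]
#' @param meta per-assay QC metadata (see [read_assay_qc()]); must cover
#'   every assay in `ct`.
#' @param margin cycles; a detected Ct `>= negctrl_ct - margin` is flagged.
#'   Default 5.
#' @param min_efficiency assays with efficiency strictly below this are
#'   removed. Default 1.6.
#' @param scope `"cell"` or `"assay"` for the negative-control rule.
#' @return list with `ct` (filtered [ct_matrix()]) and `report`, a tibble
#'   with columns `assay_id`, `sample_id` (`NA` for panel-wide removals) and
#'   `reason` (`multi_melt`, `low_efficiency`, `near_negative_control`).
#' @export
apply_assay_qc <- function(ct, meta, margin = 5, min_efficiency = 1.6,
                           scope = c("cell", "assay")) {
  scope <- match.arg(scope)
  stopifnot(inherits(ct, "ct_matrix"))
  meta <- as.data.frame(meta)
  missing <- setdiff(rownames(ct), meta$assay_id)
  if (length(missing)) {
    stop("no QC metadata for assay(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[match(rownames(ct), meta$assay_id), ]
  m <- unclass(ct)
  removed <- list()
  log_removal <- function(assay, sample, reason) {
    removed[[length(removed) + 1]] <<- data.frame(
      assay_id = assay, sample_id = sample, reason = reason,
      stringsAsFactors = FALSE)
  }

  bad_melt <- !meta$melt_ok
  bad_eff <- !bad_melt & meta$efficiency < min_efficiency
  for (i in which(bad_melt)) log_removal(rownames(m)[i], NA_character_, "multi_melt")
  for (i in which(bad_eff)) log_removal(rownames(m)[i], NA_character_, "low_efficiency")
  m[bad_melt | bad_eff, ] <- NA_real_

  survivors <- which(!(bad_melt | bad_eff))
  for (i in survivors) {
    nc <- meta$negctrl_ct[i]
    if (is.na(nc)) next
    hit <- which(!is.na(m[i, ]) & m[i, ] >= nc - margin)
    if (!length(hit)) next
    if (scope == "assay") {
      log_removal(rownames(m)[i], NA_character_, "near_negative_control")
      m[i, ] <- NA_real_
    } else {
      for (j in hit) log_removal(rownames(m)[i], colnames(m)[j],
                                 "near_negative_control")
      m[i, hit] <- NA_real_
    }
  }
  report <- if (length(removed)) {
    tibble::as_tibble(do.call(rbind, removed))
  } else {
    tibble::tibble(assay_id = character(), sample_id = character(),
                   reason = character())
  }
  list(ct = ct_matrix(m), report = report)
}

#' Detection summary
#'
#' Counts detected assays per sample and identifies the co-expressed set:
#' assays with a valid Ct in every sample. The co-expressed set is the basis
#' of the global-mean normalizer.
#'
#' @param ct a QC-filtered [ct_matrix()]
#' @return list with `detected_per_sample` (named integer vector) and
#'   `coexpressed_set` (character vector of assay ids).
#' @export
detection_summary <- function(ct) {
  stopifnot(inherits(ct, "ct_matrix"))
  det <- is_detected(ct)
  counts <- colSums(det)
  storage.mode(counts) <- "integer"
  list(detected_per_sample = counts,
       coexpressed_set = rownames(ct)[rowSums(det) == ncol(ct)])
}

#' Hemolysis indicator
#'
#' Computes the per-sample difference Ct(miR-23a-3p) − Ct(miR-451a).
#' miR-451a is highly abundant in erythrocytes, so red-cell lysis lowers its
#' Ct and inflates the difference; values above `warn_threshold` flag likely
#' hemolysis. When annotations are supplied the three diagnostic groups are
#' compared by Kruskal–Wallis, mirroring the check that plasma quality does
#' not differ systematically between groups.
#'
#' @param ct a [ct_matrix()]
#' @param annotations optional sample annotations (for the group comparison)
#' @param target,marker assay ids of the indicator pair
#' @param warn_threshold cycles; literature convention is ~7 for the
#'   23a/451a pair.
#' @return list with `delta_ct` (tibble `sample_id`, `delta_ct`, `flagged`)
#'   and `group_test` (list `H`, `p`, or `NULL` when no annotations given).
#' @export
hemolysis_delta_ct <- function(ct, annotations = NULL,
                               target = "hsa-miR-23a-3p",
                               marker = "hsa-miR-451a",
                               warn_threshold = 7) {
  stopifnot(inherits(ct, "ct_matrix"))
  for (a in c(target, marker)) {
    if (!a %in% rownames(ct)) stop("assay not in panel: ", a, call. = FALSE)
  }
  d <- unclass(ct)[target, ] - unclass(ct)[marker, ]
  out <- tibble::tibble(sample_id = colnames(ct), delta_ct = unname(d),
                        flagged = unname(!is.na(d) & d > warn_threshold))
  test <- NULL
  if (!is.null(annotations)) {
    grp <- diagnostic_group(annotations$group[match(out$sample_id,
                                                    annotations$sample_id)])
    keep <- !is.na(out$delta_ct) & !is.na(grp)
    if (length(unique(grp[keep])) >= 2) {
      test <- kruskal_wallis(out$delta_ct[keep], grp[keep])
    }
  }
  list(delta_ct = out, group_test = test)
}

#' Spike-in checks
#'
#' Verifies the RNA-extraction spike-in ladder and the reverse-transcription
#' spike-in. UniSp2/UniSp4/UniSp5 are pre-mixed at 100-fold concentration
#' steps, so at efficiency 2 consecutive Cts should differ by
#' log2(100) ≈ 6.64 cycles; deviations beyond `spacing_tol` are warned.
#' UniSp6, added at reverse transcription, should sit within `rt_band`
#' cycles of its cohort median.
#'
#' @param spikein data frame with columns `sample_id`, `UniSp2`, `UniSp4`,
#'   `UniSp5`, `UniSp6` (Ct values; any ladder column may be absent, in
#'   which case that check is skipped with a message).
#' @param spacing_tol cycles of tolerated deviation from the expected
#'   ladder spacing. Default 1.
#' @param rt_band cycles around the cohort UniSp6 median. Default 2.
#' @return tibble of warnings: `sample_id`, `check`, `message` (zero rows if
#'   all checks pass).
#' @export
spikein_check <- function(spikein, spacing_tol = 1, rt_band = 2) {
  spikein <- as.data.frame(spikein)
  expected <- log2(100)
  warnings <- list()
  add <- function(sample, check, msg) {
    warnings[[length(warnings) + 1]] <<- data.frame(
      sample_id = sample, check = check, message = msg,
      stringsAsFactors = FALSE)
  }
  ladder <- c("UniSp2", "UniSp4", "UniSp5")
  if (all(ladder %in% names(spikein))) {
    for (k in 1:2) {
      lo <- ladder[k]; hi <- ladder[k + 1]
      sp <- spikein[[hi]] - spikein[[lo]]
      off <- which(!is.na(sp) & abs(sp - expected) > spacing_tol)
      for (i in off) {
        add(spikein$sample_id[i], "extraction_ladder",
            sprintf("%s-%s spacing %.2f cycles (expected %.2f +/- %g)",
                    lo, hi, sp[i], expected, spacing_tol))
      }
    }
  } else {
    message("spike-in ladder columns absent; extraction check skipped")
  }
  if ("UniSp6" %in% names(spikein)) {
    med <- stats::median(spikein$UniSp6, na.rm = TRUE)
    off <- which(!is.na(spikein$UniSp6) & abs(spikein$UniSp6 - med) > rt_band)
    for (i in off) {
      add(spikein$sample_id[i], "rt_spikein",
          sprintf("UniSp6 Ct %.2f deviates > %g cycles from cohort median %.2f",
                  spikein$UniSp6[i], rt_band, med))
    }
  } else {
    message("UniSp6 column absent; reverse-transcription check skipped")
  }
  if (length(warnings)) tibble::as_tibble(do.call(rbind, warnings)) else
    tibble::tibble(sample_id = character(), check = character(),
                   message = character())
}
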