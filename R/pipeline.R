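#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs. Exactly one of
#' `input` (paths to a Ct table, annotation TSV, QC-metadata TSV and
#' optional spike-in TSV) or `synthetic` (a [synthetic_config()]) must be
#' supplied.
#'
#' @param input `NULL`, or list with `ct`, `annotations`, `qc`, and
#'   optionally `spikein` file paths.
#' @param synthetic `NULL`, or a [synthetic_config()].
#' @param out_dir directory for the result tables.
#' @param qc list: `margin`, `min_efficiency`, `scope`.
#' @param normalization list: `log_base`, `stability_grouped`.
#' @param contrasts named contrast list (default [DEFAULT_CONTRASTS]).
#' @param clustering list: `linkage`, `metric`.
#' @param verbose emit per-stage messages.
#' @return list of class `run_config`
#' @export
run_config <- function(input = NULL, synthetic = NULL, out_dir = tempfile("run"),
                       qc = list(margin = 5, min_efficiency = 1.6,
                                 scope = "cell"),
                       normalization = list(log_base = 10,
                                            stability_grouped = TRUE),
                       contrasts = DEFAULT_CONTRASTS,
                       clustering = list(linkage = "average",
                                         metric = "euclidean"),
                       verbose = TRUE) {
  if (is.null(input) == is.null(synthetic)) {
    stop("supply exactly one of `input` or `synthetic`", call. = FALSE)
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  if (!is.null(input)) {
    need <- c("ct", "annotations", "qc")
    if (!all(need %in% names(input))) {
      stop("`input` needs paths: ", paste(need, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(input = input, synthetic = synthetic, out_dir = out_dir,
                 qc = qc, normalization = normalization,
                 contrasts = contrasts, clustering = clustering,
                 verbose = verbose),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order: data acquisition (file input or synthetic
#' generation), assay QC, detection / hemolysis / spike-in summaries,
#' global-mean NRQ normalization with the stability ranking, per-group
#' co-regulation diagnostics, the group-contrast lattice with signature
#' selection and group clustering, and the clinical comparison table. All
#' result tables are written tab-delimited under `out_dir`; outputs are
#' pure functions of (inputs, config, seed).
#'
#' @param config a [run_config()]
#' @return list of class `run_manifest`: `files` (the [write_results()]
#'   manifest), `metrics` (headline numbers per stage), `config`, and
#'   `objects` (the in-memory stage results).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (isTRUE(config$verbose)) message("[miRpanel] ", ...)

  if (!is.null(config$synthetic)) {
    say("stage input: generating synthetic cohort (seed ",
        config$synthetic$seed, ")")
    cohort <- generate_cohort(config$synthetic)
    ct <- cohort$ct; ann <- cohort$annotations
    qc_meta <- cohort$qc_meta; spikein <- cohort$spikein
  } else {
    say("stage input: reading ", config$input$ct)
    ct <- read_ct_table(config$input$ct)
    ann <- read_annotations(config$input$annotations, ct = ct)
    qc_meta <- read_assay_qc(config$input$qc)
    spikein <- if (!is.null(config$input$spikein)) {
      sp <- utils::read.delim(config$input$spikein, check.names = FALSE)
      tibble::as_tibble(sp)
    }
  }

  say("stage qc: margin ", config$qc$margin, ", min efficiency ",
      config$qc$min_efficiency)
  qc <- apply_assay_qc(ct, qc_meta, margin = config$qc$margin,
                       min_efficiency = config$qc$min_efficiency,
                       scope = config$qc$scope)
  det <- detection_summary(qc$ct)
  say("stage qc: mean detected/sample ",
      round(mean(det$detected_per_sample), 1), "; co-expressed ",
      length(det$coexpressed_set))
  hemo <- hemolysis_delta_ct(qc$ct, ann)
  spike <- if (!is.null(spikein)) spikein_check(spikein)

  say("stage normalization: global-mean NRQ, log base ",
      config$normalization$log_base)
  gm <- global_mean(qc$ct, det$coexpressed_set)
  lognrq <- nrq(qc$ct, gm, log_base = config$normalization$log_base)
  log2q <- -unclass(qc$ct)[det$coexpressed_set, , drop = FALSE]
  stab <- stability_scores(log2q, diagnostic_group(
    ann$group[match(colnames(qc$ct), ann$sample_id)]),
    grouped = isTRUE(config$normalization$stability_grouped))

  say("stage coregulation: per-group correlation profiles")
  prof <- correlation_profiles(qc$ct, ann, det$coexpressed_set)
  trend <- group_quantity_trend(qc$ct, ann, det$coexpressed_set)

  say("stage differential: ", length(config$contrasts), " contrasts")
  contrasts <- run_contrasts(lognrq, ann, contrasts = config$contrasts)
  signature <- select_signature(contrasts)
  say("stage differential: signature size ", length(signature))
  dend <- if (length(signature) >= 1 && length(unique(ann$group)) >= 2) {
    cluster_groups(lognrq, ann, signature,
                   linkage = config$clustering$linkage,
                   metric = config$clustering$metric)
  }

  say("stage clinical: group comparison table")
  clin <- clinical_table(ann)

  mean_r <- vapply(prof$profiles, `[[`, 1, "mean_r")
  tables <- list(
    qc_report = qc$report,
    detection = tibble::tibble(sample_id = names(det$detected_per_sample),
                               n_detected = unname(det$detected_per_sample)),
    hemolysis = hemo$delta_ct,
    global_mean = tibble::tibble(sample_id = names(gm), mean_ct = unname(gm)),
    stability = stab,
    group_mean_r = tibble::tibble(group = names(mean_r),
                                  mean_r = unname(mean_r)),
    quantity_trend = trend,
    contrast_table = contrasts,
    signature = tibble::tibble(assay_id = signature),
    clinical_table = clin
  )
  if (!is.null(spike)) tables$spikein_warnings <- spike
  if (!is.null(dend)) tables$dendrogram <-
      tibble::tibble(newick = dend$newick, linkage = dend$linkage,
                     metric = dend$metric)
  files <- write_results(tables, config$out_dir)

  metrics <- list(
    n_assays = nrow(ct), n_samples = ncol(ct),
    n_removed = nrow(qc$report),
    mean_detected = mean(det$detected_per_sample),
    n_coexpressed = length(det$coexpressed_set),
    top_stability_candidate = stab$candidate_id[1],
    hemolysis_kw_p = if (!is.null(hemo$group_test)) hemo$group_test$p,
    mean_r_by_group = mean_r,
    n_significant = sum(contrasts$category != "n.s."),
    signature_size = length(signature),
    newick = if (!is.null(dend)) dend$newick
  )
  structure(list(files = files, metrics = metrics, config = config,
                 objects = list(ct = qc$ct, annotations = ann,
                                lognrq = lognrq, detection = det,
                                stability = stab, profiles = prof,
                                contrasts = contrasts,
                                signature = signature, dendrogram = dend)),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat(sprintf("  %d assays x %d samples; %d co-expressed; signature %d\n",
              x$metrics$n_assays, x$metrics$n_samples,
              x$metrics$n_coexpressed, x$metrics$signature_size))
  cat(sprintf("  %d result files under %s\n", nrow(x$files),
              x$config$out_dir))
  invisible(x)
}
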