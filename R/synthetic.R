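#' Default differential-expression effects
#'
#' Ground-truth Ct shifts (cycles; positive = later Ct = down-regulated)
#' echoing the qualitative contrast pattern of the modelled cohort: a block
#' of non-progressor-specific effects (mostly decreased, two increased), a
#' small block modulated in T2D with the progressor subgroup close to T2D
#' and the non-progressors barely affected, and a block separating
#' non-progressors from progressors.
#'
#' @return tibble: `assay_id`, `group`, `shift_cycles`
#' @export
default_de_effects <- function() {
  np <- paste0("sim-miR-", sprintf("%03d", 10:18))
  np_shift <- c(-1.2, -1.2, 1.2, 1.0, 1.2, 0.8, 1.0, 1.2, 1.0)
  t2d <- paste0("sim-miR-", sprintf("%03d", 19:21))
  t2d_shift <- c(-1.0, 1.0, -1.0)
  npvp <- paste0("sim-miR-", sprintf("%03d", 22:24))
  npvp_shift <- c(1.0, -1.0, -1.0)
  tibble::tibble(
    assay_id = c(np, rep(t2d, 3), npvp),
    group = c(rep("NP_IGT", length(np)),
              rep(c("T2D", "P_IGT", "NP_IGT"), each = length(t2d)),
              rep("NP_IGT", length(npvp))),
    shift_cycles = c(np_shift, t2d_shift, 0.8 * t2d_shift, 0.2 * t2d_shift,
                     npvp_shift)
  )
}

#' Synthetic cohort configuration
#'
#' Full generative parameterization of a simulated plasma miRNA panel
#' cohort. The generative model for assay `a` in sample `s` of group `g`
#' is
#' \deqn{Ct_{as} = \mu_a - shift_g + \lambda_{ag} f_s + \delta_{ag} +
#'   \epsilon_{as}}
#' with a standard-normal per-sample latent factor `f_s` (the shared
#' plasma miRNA concentration signal), loadings
#' `\lambda ~ N(1, factor_loading_sd_g^2)` whose group-wise dispersion
#' controls how tightly assays co-regulate, group concentration shifts
#' (cycles subtracted from every Ct), assay/group differential effects
#' `\delta`, and residual noise. Cells beyond `lod_ct` are censored to the
#' undetected state.
#'
#' Baseline mean Cts are drawn from a two-component profile — an abundant
#' block well below the detection limit and a borderline block just under
#' it — calibrated so a default cohort shows roughly 160 detected assays
#' per sample with roughly 90 detected in all samples, the detection
#' structure typical of plasma panels of this size.
#'
#' @param seed integer seed; identical seed and config give bit-identical
#'   cohorts.
#' @param n_per_group named counts for NGT / NP_IGT / P_IGT / T2D.
#' @param n_assays panel size (default 179).
#' @param n_abundant assays in the abundant baseline block.
#' @param abundant_range,borderline_range Ct ranges of the two baseline
#'   blocks.
#' @param global_shift named per-group concentration effect, cycles
#'   subtracted from all Cts.
#' @param factor_loading_sd named per-group SD of the latent-factor
#'   loadings; larger values weaken within-group co-regulation.
#' @param de_effects tibble of injected effects (see
#'   [default_de_effects()]); `NULL` for none.
#' @param noise_sd residual Ct SD (cycles).
#' @param lod_ct detection ceiling (cycles).
#' @param hemolysis_samples sample ids whose red-cell marker
#'   (hsa-miR-451a) Ct is lowered by `hemolysis_shift` cycles.
#' @param hemolysis_shift cycles of marker drop in hemolyzed samples.
#' @param coupling_assays assays whose latent-factor loading is pinned to
#'   `coupling_slopes` per group (local-vs-global slope truth).
#' @param coupling_slopes named per-group loading for the coupled assays.
#' @param n_bad_melt,n_low_efficiency,n_near_negctrl borderline-block
#'   assays planted to fail each QC filter.
#' @param spike_base Ct of the most concentrated extraction spike-in.
#' @param spike_noise_sd Ct noise on spike-ins.
#' @param unisp6_ct mean Ct of the reverse-transcription spike-in.
#' @return validated list of class `synthetic_config`
#' @export
synthetic_config <- function(seed = 1,
                             n_per_group = c(NGT = 9, NP_IGT = 4,
                                             P_IGT = 5, T2D = 9),
                             n_assays = 179,
                             n_abundant = 60,
                             abundant_range = c(20, 33),
                             borderline_range = c(34.5, 37.5),
                             global_shift = c(NGT = 0, NP_IGT = 0.7,
                                              P_IGT = 0.7, T2D = 0.9),
                             factor_loading_sd = c(NGT = 0.2, NP_IGT = 0.55,
                                                   P_IGT = 0.55, T2D = 0.25),
                             de_effects = default_de_effects(),
                             noise_sd = 0.4,
                             lod_ct = 37,
                             hemolysis_samples = character(),
                             hemolysis_shift = 5,
                             coupling_assays = "hsa-miR-27a-3p",
                             coupling_slopes = c(NGT = 1.0, NP_IGT = 0.6,
                                                 P_IGT = 0.6, T2D = 0.3),
                             n_bad_melt = 2, n_low_efficiency = 2,
                             n_near_negctrl = 2,
                             spike_base = 19, spike_noise_sd = 0.15,
                             unisp6_ct = 21) {
  cf <- mget(setdiff(names(formals()), ""), environment())
  for (nm in list(n_per_group, global_shift, factor_loading_sd,
                  coupling_slopes)) {
    if (!all(GROUP_LEVELS %in% names(nm))) {
      stop("per-group parameters need names ",
           paste(GROUP_LEVELS, collapse = ", "), call. = FALSE)
    }
  }
  if (any(n_per_group <= 0)) stop("group sizes must be positive", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (lod_ct <= 0 || lod_ct > 50) stop("lod_ct must be in (0, 50]", call. = FALSE)
  if (!is.null(de_effects)) {
    bad <- setdiff(unique(de_effects$group), GROUP_LEVELS)
    if (length(bad)) stop("de_effects has unknown group(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(cf, class = "synthetic_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

synthetic_assay_names <- function(n_assays) {
  ids <- paste0("sim-miR-", sprintf("%03d", seq_len(n_assays)))
  # designated panel members used by QC and coupling diagnostics
  ids[1] <- "hsa-miR-23a-3p"
  ids[2] <- "hsa-miR-451a"
  ids[3] <- "hsa-miR-27a-3p"
  ids
}

rlnorm_match <- function(n, m, s) {
  # log-normal with the requested mean and SD
  sdlog <- sqrt(log(1 + (s / m)^2))
  stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
}

#' Generate a synthetic cohort
#'
#' Draws a complete cohort — Ct matrix, per-assay QC metadata, spike-in
#' table, sample annotations with clinical covariates — from a
#' [synthetic_config()]. Clinical covariates are drawn per diagnostic group
#' from the bundled reference summaries ([table1_reference()]): normal for
#' near-symmetric variables, log-normal (matched mean/SD) for the skewed
#' ones, with the HOMA index computed from the drawn glucose and insulin
#' (conventional formula) rather than drawn independently.
#'
#' @param config a [synthetic_config()]
#' @return list of class `synthetic_cohort`: `ct` ([ct_matrix()]),
#'   `qc_meta`, `spikein`, `annotations`, `truth` ([truth_table()]),
#'   `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  with_seed(cf$seed, {
    n_assays <- cf$n_assays
    assays <- synthetic_assay_names(n_assays)
    groups <- rep(GROUP_LEVELS, cf$n_per_group[GROUP_LEVELS])
    n_samples <- length(groups)
    samples <- sprintf("S%02d", seq_len(n_samples))

    n_border <- n_assays - cf$n_abundant
    mu <- c(stats::runif(cf$n_abundant, cf$abundant_range[1], cf$abundant_range[2]),
            stats::runif(n_border, cf$borderline_range[1], cf$borderline_range[2]))
    names(mu) <- assays
    # typical plasma Cts for the designated assays: the hemolysis pair sits
    # a few cycles apart so the delta-Ct indicator has a realistic baseline
    mu["hsa-miR-23a-3p"] <- 24
    mu["hsa-miR-451a"] <- 21
    mu["hsa-miR-27a-3p"] <- 26

    # loadings per assay x group
    lambda <- sapply(GROUP_LEVELS, function(g)
      stats::rnorm(n_assays, 1, cf$factor_loading_sd[[g]]))
    rownames(lambda) <- assays
    for (a in intersect(cf$coupling_assays, assays)) {
      lambda[a, ] <- cf$coupling_slopes[colnames(lambda)]
    }

    delta <- matrix(0, n_assays, length(GROUP_LEVELS),
                    dimnames = list(assays, GROUP_LEVELS))
    if (!is.null(cf$de_effects) && nrow(cf$de_effects)) {
      for (i in seq_len(nrow(cf$de_effects))) {
        delta[cf$de_effects$assay_id[i], cf$de_effects$group[i]] <-
          delta[cf$de_effects$assay_id[i], cf$de_effects$group[i]] +
          cf$de_effects$shift_cycles[i]
      }
    }

    f <- stats::rnorm(n_samples)
    eps <- matrix(stats::rnorm(n_assays * n_samples, 0, cf$noise_sd),
                  n_assays, n_samples)
    ct <- matrix(NA_real_, n_assays, n_samples,
                 dimnames = list(assays, samples))
    for (j in seq_len(n_samples)) {
      g <- groups[j]
      ct[, j] <- mu - cf$global_shift[[g]] + lambda[, g] * f[j] +
        delta[, g] + eps[, j]
    }
    hem <- intersect(cf$hemolysis_samples, samples)
    if (length(hem)) ct["hsa-miR-451a", hem] <-
        ct["hsa-miR-451a", hem] - cf$hemolysis_shift
    ct[ct > cf$lod_ct] <- NA_real_
    ct <- pmin(pmax(ct, 1), 50)  # guard the valid Ct range
    dim(ct) <- c(n_assays, n_samples)
    dimnames(ct) <- list(assays, samples)

    # planted QC failures live at the end of the borderline block so the
    # designated and effect-carrying assays stay intact
    idx <- n_assays
    take <- function(n) {
      if (n == 0) return(integer(0))
      out <- seq.int(idx - n + 1L, idx)
      idx <<- idx - n
      out
    }
    bad_melt <- take(cf$n_bad_melt)
    low_eff <- take(cf$n_low_efficiency)
    near_nc <- take(cf$n_near_negctrl)
    efficiency <- stats::runif(n_assays, 1.75, 2.0)
    efficiency[low_eff] <- stats::runif(cf$n_low_efficiency, 1.35, 1.55)
    melt_ok <- rep(TRUE, n_assays)
    melt_ok[bad_melt] <- FALSE
    negctrl <- stats::runif(n_assays, 43, 46)
    negctrl[near_nc] <- mu[near_nc] + 3  # within the 5-cycle margin
    qc_meta <- tibble::tibble(assay_id = assays, efficiency = efficiency,
                              melt_ok = melt_ok, negctrl_ct = negctrl)

    spacing <- log2(100)
    spikein <- tibble::tibble(
      sample_id = samples,
      UniSp2 = cf$spike_base + stats::rnorm(n_samples, 0, cf$spike_noise_sd),
      UniSp4 = cf$spike_base + spacing +
        stats::rnorm(n_samples, 0, cf$spike_noise_sd),
      UniSp5 = cf$spike_base + 2 * spacing +
        stats::rnorm(n_samples, 0, cf$spike_noise_sd),
      UniSp6 = cf$unisp6_ct + stats::rnorm(n_samples, 0, cf$spike_noise_sd)
    )

    tb <- table1_reference()
    diag_grp <- diagnostic_group(groups)
    col_of <- c(NGT = "ngt", IGT = "igt", T2D = "t2d")
    clin <- list()
    draw_var <- function(variable, skewed) {
      vapply(diag_grp, function(g) {
        m <- tb[[paste0(col_of[[g]], "_mean")]][tb$variable == variable]
        s <- tb[[paste0(col_of[[g]], "_sd")]][tb$variable == variable]
        if (skewed) rlnorm_match(1, m, s) else abs(stats::rnorm(1, m, s))
      }, 1)
    }
    skewed_vars <- c("insulin", "microalbuminuria", "triglycerides")
    for (v in setdiff(tb$variable, "homa")) {
      clin[[v]] <- draw_var(v, v %in% skewed_vars)
    }
    clin$homa <- homa_ir(clin$fasting_glucose, clin$insulin, "conventional")
    pct <- gender_reference()$pct_males
    sex <- ifelse(stats::runif(n_samples) < pct[diag_grp] / 100, "M", "F")
    annotations <- tibble::tibble(sample_id = samples, group = groups,
                                  sex = sex)
    for (v in names(clin)) annotations[[v]] <- unname(clin[[v]])

    structure(list(ct = ct_matrix(ct), qc_meta = qc_meta, spikein = spikein,
                   annotations = annotations, truth = truth_table(cf),
                   config = cf),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d assays x %d samples (seed %d)\n",
              nrow(x$ct), ncol(x$ct), x$config$seed))
  invisible(x)
}

#' Ground truth of a synthetic configuration
#'
#' Machine-readable record of what was injected: differential effects per
#' assay and group, coupling slopes of the designated assays, and the
#' per-group global concentration shifts — the key for parameter-recovery
#' tests.
#'
#' @param config a [synthetic_config()]
#' @return list: `de` (tibble `assay_id`, `group`, `shift_cycles`,
#'   `direction`; up = more miRNA = lower Ct), `slopes`, `global_shift`.
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  de <- config$de_effects
  de_out <- if (is.null(de) || !nrow(de)) {
    tibble::tibble(assay_id = character(), group = character(),
                   shift_cycles = numeric(), direction = character())
  } else {
    tibble::tibble(assay_id = de$assay_id, group = de$group,
                   shift_cycles = de$shift_cycles,
                   direction = ifelse(de$shift_cycles < 0, "up", "down"))
  }
  slopes <- do.call(rbind, lapply(config$coupling_assays, function(a) {
    tibble::tibble(assay_id = a, group = GROUP_LEVELS,
                   slope = unname(config$coupling_slopes[GROUP_LEVELS]))
  }))
  list(de = de_out, slopes = slopes,
       global_shift = tibble::tibble(
         group = GROUP_LEVELS,
         shift = unname(config$global_shift[GROUP_LEVELS])))
}
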