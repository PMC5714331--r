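# Small fixtures shared across test files; everything is built in code.

tiny_ct <- function() {
  ct_matrix(matrix(c(20, 25, 30, NA), nrow = 2, byrow = TRUE,
                   dimnames = list(c("miR-a", "miR-b"), c("S1", "S2"))))
}

# a fully detected matrix with controllable values
make_ct <- function(values, assays = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(assays)) assays <- paste0("miR-", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(m)))
  dimnames(m) <- list(assays, samples)
  ct_matrix(m)
}

make_annotations <- function(samples, groups, ...) {
  ann <- tibble::tibble(sample_id = samples, group = groups)
  extra <- list(...)
  for (v in names(extra)) ann[[v]] <- extra[[v]]
  ann
}

qc_meta_ok <- function(assays) {
  tibble::tibble(assay_id = assays, efficiency = 1.9, melt_ok = TRUE,
                 negctrl_ct = NA_real_)
}

# small fast synthetic config for tests that only need structure
small_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_assays = 60, n_abundant = 40,
                   n_bad_melt = 1, n_low_efficiency = 1, n_near_negctrl = 1,
                   ...)
}

# average-rank vector computed by explicit enumeration (oracle helper)
brute_ranks <- function(x) {
  sapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  })
}
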