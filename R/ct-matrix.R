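#' Construct a Ct matrix
#'
#' A `ct_matrix` is a numeric assay-by-sample grid of raw quantification-cycle
#' (Ct, also written Cq) values. Undetected reactions are stored explicitly as
#' `NA`; they are never encoded as a sentinel cycle number. Lower Ct means more
#' template.
#'
#' @param ct numeric matrix, rows = assays, columns = samples. `NA` marks an
#'   undetected cell.
#' @param assay_ids,sample_ids character vectors of unique row/column names;
#'   default taken from `dimnames(ct)`.
#' @return a numeric matrix of class `ct_matrix` with assay row names and
#'   sample column names.
#' @examples
#' m <- matrix(c(20, 25, 30, NA), 2, 2,
#'             dimnames = list(c("miR-a", "miR-b"), c("S1", "S2")))
#' ct_matrix(m)
#' @export
ct_matrix <- function(ct, assay_ids = rownames(ct), sample_ids = colnames(ct)) {
  if (!is.matrix(ct) || !is.numeric(ct)) {
    stop("`ct` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(assay_ids) || is.null(sample_ids)) {
    stop("assay and sample ids are required (rownames/colnames or arguments)",
         call. = FALSE)
  }
  assay_ids <- as.character(assay_ids)
  sample_ids <- as.character(sample_ids)
  if (length(assay_ids) != nrow(ct) || length(sample_ids) != ncol(ct)) {
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(assay_ids)) {
    stop("duplicate assay ids: ",
         paste(unique(assay_ids[duplicated(assay_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  detected <- ct[!is.na(ct)]
  if (length(detected) && (any(!is.finite(detected)) ||
                           any(detected <= 0) || any(detected > 50))) {
    stop("detected Ct values must be finite and in (0, 50]", call. = FALSE)
  }
  dimnames(ct) <- list(assay_ids, sample_ids)
  class(ct) <- c("ct_matrix", class(ct))
  ct
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("<ct_matrix> %d assays x %d samples; %d undetected cells (%.1f%%)\n",
              nrow(x), ncol(x), sum(is.na(x)), 100 * mean(is.na(x))))
  invisible(x)
}

#' Which cells hold a detected Ct value
#' @param ct a [ct_matrix()]
#' @return logical matrix, `TRUE` where a Ct was measured.
#' @export
is_detected <- function(ct) !is.na(unclass(ct))

# Split one delimited line; the sentinel keeps trailing empty fields.
split_fields <- function(line, sep) {
  out <- strsplit(paste0(line, sep, "\x01"), sep, fixed = TRUE)[[1]]
  out[-length(out)]
}

read_table_lines <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (inherits(source, "connection")) {
    readLines(source, warn = FALSE)
  } else {
    # literal text block
    strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  lines[!(seq_along(lines) > 1 & lines == "" &
            seq_along(lines) == length(lines))] # drop single trailing blank line
}

#' Read a Ct panel table
#'
#' Parses the tab- (or comma-) delimited export convention of miRNA PCR
#' panels: a header row of sample ids, a first column of assay ids, and one
#' Ct value per cell. Cells matching `undetected_tokens` (and, optionally,
#' values at or above `ct_ceiling`) become the undetected state.
#'
#' @param source path to a file, a connection, or a character vector holding
#'   the table text.
#' @param dialect `"tab"` or `"csv"`.
#' @param undetected_tokens strings mapped to the undetected state.
#' @param ct_ceiling optional cycle threshold; detected values `>=` this are
#'   re-coded as undetected (some instrument exports use e.g. 40 as a
#'   sentinel). Default `NULL`: no ceiling.
#' @param transpose set `TRUE` if the file stores samples in rows.
#' @return a [ct_matrix()]
#' @export
read_ct_table <- function(source, dialect = c("tab", "csv"),
                          undetected_tokens = c("", "NA", "Undetermined"),
                          ct_ceiling = NULL, transpose = FALSE) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tab") "\t" else ","
  lines <- read_table_lines(source)
  if (length(lines) < 2) stop("Ct table needs a header row and at least one assay row",
                              call. = FALSE)
  fields <- lapply(lines, split_fields, sep = sep)
  width <- length(fields[[1]])
  bad <- which(vapply(fields, length, 1L) != width)
  if (length(bad)) {
    stop(sprintf("ragged table: line %d has %d fields, expected %d",
                 bad[1], length(fields[[bad[1]]]), width), call. = FALSE)
  }
  header <- fields[[1]][-1]
  body <- fields[-1]
  row_ids <- vapply(body, `[[`, "", 1L)
  cells <- t(vapply(body, function(f) f[-1], character(width - 1L)))
  if (width == 2L) cells <- matrix(cells, ncol = 1L) # vapply drops dim
  und <- matrix(cells %in% undetected_tokens, nrow = nrow(cells))
  vals <- suppressWarnings(as.numeric(cells))
  bad_cell <- which(!und & is.na(vals))
  if (length(bad_cell)) {
    rc <- arrayInd(bad_cell[1], dim(und))
    stop(sprintf("cannot parse Ct value '%s' at assay row %d, sample column %d",
                 cells[bad_cell[1]], rc[1], rc[2]), call. = FALSE)
  }
  vals[und] <- NA_real_
  dim(vals) <- dim(und)
  if (!is.null(ct_ceiling)) vals[!is.na(vals) & vals >= ct_ceiling] <- NA_real_
  m <- vals
  rownames(m) <- row_ids
  colnames(m) <- header
  if (transpose) m <- t(m)
  ct_matrix(m)
}

#' Write a Ct panel table
#'
#' Inverse of [read_ct_table()]: rows = assays, columns = samples, undetected
#' cells written as `undetected_token`. Values are printed at full double
#' precision so a read/write round trip is lossless.
#'
#' @param ct a [ct_matrix()]
#' @param path output file path
#' @param undetected_token string for undetected cells (default `"NA"`)
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path, undetected_token = "NA") {
  stopifnot(inherits(ct, "ct_matrix"))
  m <- unclass(ct)
  chr <- matrix(vapply(m, function(v) {
    if (is.na(v)) undetected_token else format(v, digits = 15)
  }, ""), nrow = nrow(m))
  lines <- c(paste(c("assay_id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], chr[i, ]), collapse = "\t")
             }, ""))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Progression-group levels
#'
#' Four-level split used throughout: normal glucose tolerance (`NGT`),
#' impaired glucose tolerance divided into non-progressors (`NP_IGT`) and
#' progressors (`P_IGT`) by diabetes diagnosis during follow-up, and newly
#' diagnosed type 2 diabetes (`T2D`).
#' @export
GROUP_LEVELS <- c("NGT", "NP_IGT", "P_IGT", "T2D")

#' Collapse progression groups to the three diagnostic groups
#'
#' `NP_IGT` and `P_IGT` form the `IGT` umbrella; `NGT` and `T2D` are
#' unchanged.
#' @param group character vector of four-level group labels
#' @return character vector with levels `NGT`, `IGT`, `T2D`
#' @export
diagnostic_group <- function(group) {
  out <- ifelse(group %in% c("NP_IGT", "P_IGT"), "IGT", group)
  bad <- setdiff(unique(group), GROUP_LEVELS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out
}

#' Read per-sample annotations
#'
#' One row per sample with columns `sample_id`, `group` (one of
#' `r paste(GROUP_LEVELS, collapse = ", ")`), `sex` (`M`/`F`), and any number
#' of numeric clinical covariate columns. Empty clinical cells are recorded as
#' missing, never as zero.
#'
#' @param source path, connection, or character vector with the TSV text.
#' @param ct optional companion [ct_matrix()]; sample ids absent from it are
#'   reported with a warning.
#' @return a [tibble::tibble] with one row per sample.
#' @export
read_annotations <- function(source, ct = NULL) {
  lines <- read_table_lines(source)
  fields <- lapply(lines, split_fields, sep = "\t")
  width <- length(fields[[1]])
  bad <- which(vapply(fields, length, 1L) != width)
  if (length(bad)) stop(sprintf("ragged annotation table at line %d", bad[1]),
                        call. = FALSE)
  header <- fields[[1]]
  need <- c("sample_id", "group")
  if (!all(need %in% header)) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  body <- fields[-1]
  df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(df) <- header
  bad_grp <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad_grp)) {
    stop("unknown group token(s): ", paste(bad_grp, collapse = ", "),
         call. = FALSE)
  }
  clinical_cols <- setdiff(header, c("sample_id", "group", "sex"))
  for (col in clinical_cols) {
    raw <- df[[col]]
    empty <- raw %in% c("", "NA")
    num <- suppressWarnings(as.numeric(raw))
    bad_num <- which(!empty & is.na(num))
    if (length(bad_num)) {
      stop(sprintf("unparseable numeric '%s' in column '%s', row %d",
                   raw[bad_num[1]], col, bad_num[1]), call. = FALSE)
    }
    if (any(num < 0, na.rm = TRUE)) {
      stop(sprintf("negative clinical value in column '%s'", col), call. = FALSE)
    }
    num[empty] <- NA_real_
    df[[col]] <- num
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in annotations",
                                        call. = FALSE)
  if (!is.null(ct)) {
    missing <- setdiff(df$sample_id, colnames(ct))
    if (length(missing)) {
      warning("annotation sample(s) absent from Ct matrix: ",
              paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' Read per-assay QC metadata
#'
#' TSV with columns `assay_id`, `efficiency` (amplification efficiency, > 0),
#' `melt_ok` (`TRUE` if the melting curve shows a single in-spec melting
#' point), and `negctrl_ct` (negative-control Ct; `NA` if the control did not
#' amplify).
#'
#' @inheritParams read_annotations
#' @return a tibble with one row per assay.
#' @export
read_assay_qc <- function(source) {
  lines <- read_table_lines(source)
  fields <- lapply(lines, split_fields, sep = "\t")
  header <- fields[[1]]
  need <- c("assay_id", "efficiency", "melt_ok", "negctrl_ct")
  if (!all(need %in% header)) {
    stop("QC metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(do.call(rbind, fields[-1]), stringsAsFactors = FALSE)
  names(df) <- header
  df$efficiency <- as.numeric(df$efficiency)
  if (any(!is.finite(df$efficiency)) || any(df$efficiency <= 0)) {
    stop("efficiency must be a positive number for every assay", call. = FALSE)
  }
  df$melt_ok <- df$melt_ok %in% c("TRUE", "true", "1", "yes")
  nc <- df$negctrl_ct
  df$negctrl_ct <- suppressWarnings(as.numeric(ifelse(nc %in% c("", "NA"), NA, nc)))
  tibble::as_tibble(df)
}

#' Write result tables
#'
#' Writes each table in a named list as a tab-delimited UTF-8 file
#' `<name>.tsv` with a single header row and stable column order, so
#' repeated runs with the same inputs are byte-identical.
#'
#' @param tables named list of data frames
#' @param out_dir output directory (created if needed)
#' @return tibble manifest: `name`, `path`, `n_rows`.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create output directory: ",
                                          out_dir, call. = FALSE)
  }
  paths <- character(length(tables))
  for (i in seq_along(tables)) {
    p <- file.path(out_dir, paste0(names(tables)[i], ".tsv"))
    df <- as.data.frame(tables[[i]])
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) ifelse(is.na(v), NA, format(v, digits = 15, trim = TRUE)))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA", fileEncoding = "UTF-8")
    paths[i] <- p
  }
  tibble::tibble(name = names(tables), path = paths,
                 n_rows = vapply(tables, nrow, 1L))
}
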