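#' Read / write a count matrix
#'
#' TSV layout: header `amplicon_id<TAB>cell1<TAB>...`, one row per amplicon,
#' numeric body. Row and column order are preserved exactly.
#'
#' @param path file path.
#' @return a validated count matrix (amplicons x cells).
#' @export
read_count_matrix <- function(path) {
  df <- read_matrix_tsv(path, "amplicon_id")
  count_matrix(df)
}

#' @rdname read_count_matrix
#' @param x count matrix to write.
#' @export
write_count_matrix <- function(x, path) {
  write_matrix_tsv(x, path, "amplicon_id")
}

#' Read / write a B-allele-frequency table
#'
#' TSV layout: header `variant_id<TAB>cell1<TAB>...`, values in \[0, 1\],
#' missing values as empty fields or "NA".
#'
#' @param path file path.
#' @return a validated BAF matrix (variants x cells).
#' @export
read_baf_table <- function(path) {
  baf_table(read_matrix_tsv(path, "variant_id"))
}

#' @rdname read_baf_table
#' @param x BAF matrix to write.
#' @export
write_baf_table <- function(x, path) {
  write_matrix_tsv(x, path, "variant_id")
}

# Shared numeric-matrix TSV reader with informative failure locations.
read_matrix_tsv <- function(path, id_col) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (!ncol(df) || names(df)[1L] != id_col) {
    stop_load("%s: expected first header column '%s', found '%s'",
              path, id_col, if (ncol(df)) names(df)[1L] else "<none>")
  }
  ids <- df[[1L]]
  body <- df[-1L]
  cells <- names(body)
  if (anyDuplicated(cells)) {
    stop_load("%s: duplicate column id '%s'", path, cells[duplicated(cells)][1L])
  }
  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(cells),
              dimnames = list(ids, cells))
  for (j in seq_along(body)) {
    v <- body[[j]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "NA")
    if (length(bad)) {
      stop_load("%s: non-numeric value '%s' in row '%s', column '%s'",
                path, v[bad[1L]], ids[bad[1L]], cells[j])
    }
    m[, j] <- num
  }
  m
}

write_matrix_tsv <- function(x, path, id_col) {
  df <- data.frame(id = rownames(x), as.data.frame(unclass(x),
                                                   check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an amplicon panel
#'
#' `panel.tsv` has columns amplicon_id, chrom, start, end; `variants.tsv`
#' has columns variant_id, amplicon_id, pos. Coordinates are 1-based
#' inclusive. File order is preserved; use [sort_panel()] for genome order.
#'
#' @param panel_path path to the amplicon table.
#' @param variants_path optional path to the variant table.
#' @return an `amplicon_panel`.
#' @export
read_panel <- function(panel_path, variants_path = NULL) {
  amp <- utils::read.delim(panel_path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  var <- if (!is.null(variants_path)) {
    utils::read.delim(variants_path, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  amplicon_panel(amp, var)
}

#' @rdname read_panel
#' @param panel panel to write.
#' @export
write_panel <- function(panel, panel_path, variants_path = NULL) {
  utils::write.table(panel$amplicons, panel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(variants_path)) {
    utils::write.table(panel$variants, variants_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(panel_path)
}

#' Read / write a reference specification
#'
#' JSON layout:
#' `{"reference_cells": ["c1", ...], "reference_cn": {"10": 3}}`.
#' Chromosome keys are strings; chromosomes omitted from `reference_cn`
#' default to copy number 2.
#'
#' @param path file path.
#' @return a `reference_spec`.
#' @export
read_reference_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cn <- obj$reference_cn
  cn_vec <- if (is.null(cn) || !length(cn)) integer() else unlist(cn)
  reference_spec(obj$reference_cells, cn_vec)
}

#' @rdname read_reference_spec
#' @param spec reference spec to write.
#' @export
write_reference_spec <- function(spec, path) {
  cn <- as.list(spec$reference_cn)
  obj <- list(reference_cells = spec$reference_cells,
              reference_cn = if (length(cn)) cn else structure(list(),
                                                               names = character()))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write copy-number calls
#'
#' `calls.tsv`: first column `cell_id`, remaining columns one per
#' chromosome, integer entries in 1..5. The same format stores simulated
#' ground truth (`truth.tsv`).
#'
#' @param path file path.
#' @return a `callset`.
#' @export
read_callset <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "cell_id") {
    stop_load("%s: expected first column 'cell_id'", path)
  }
  m <- as.matrix(df[-1L])
  rownames(m) <- df[[1L]]
  callset(m)
}

#' @rdname read_callset
#' @param calls call set to write.
#' @export
write_callset <- function(calls, path) {
  df <- data.frame(cell_id = rownames(calls),
                   as.data.frame(unclass(calls), check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a metric report to JSON
#'
#' One key per metric; the confusion matrix is written as a nested array.
#'
#' @param report a metric report list as returned by [cnv_metrics()].
#' @param path output path.
#' @export
write_metrics <- function(report, path) {
  out <- unclass(report)
  if (!is.null(out$confusion)) out$confusion <- unclass(out$confusion)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
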