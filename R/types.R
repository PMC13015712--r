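#' Construct and validate a count matrix
#'
#' A count matrix is a plain numeric matrix with amplicons as rows and cells
#' as columns; row names hold amplicon identifiers, column names cell
#' identifiers. Raw matrices contain non-negative integer read counts;
#' normalized matrices contain non-negative reals.
#'
#' @param values numeric matrix, amplicons x cells, with dimnames.
#' @return the validated matrix (invisibly classed as `count_matrix` for
#'   printing; it behaves as an ordinary matrix otherwise).
#' @export
count_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  amp <- rownames(values)
  cells <- colnames(values)
  if (is.null(amp) || is.null(cells)) {
    stop_load("count matrix requires amplicon row names and cell column names")
  }
  if (anyDuplicated(amp)) {
    stop_load("duplicate amplicon id: %s", amp[duplicated(amp)][1L])
  }
  if (anyDuplicated(cells)) {
    stop_load("duplicate cell id: %s", cells[duplicated(cells)][1L])
  }
  if (anyNA(values)) stop_load("count matrix contains missing values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop_load("negative value at amplicon '%s', cell '%s'",
              amp[bad[1L]], cells[bad[2L]])
  }
  values
}

#' Construct and validate an allele-frequency table
#'
#' Variant x cell matrix of B-allele frequencies in \[0, 1\]. Missing values
#' (NA) are allowed and are excluded from likelihoods downstream.
#'
#' @param values numeric matrix, variants x cells, with dimnames.
#' @return the validated matrix.
#' @export
baf_table <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_load("BAF table requires variant row names and cell column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop_load("duplicate variant id: %s",
              rownames(values)[duplicated(rownames(values))][1L])
  }
  ok <- is.na(values) | (values >= 0 & values <= 1)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop_load("BAF value outside [0,1] at variant '%s', cell '%s'",
              rownames(values)[bad[1L]], colnames(values)[bad[2L]])
  }
  values
}

#' Construct an amplicon panel
#'
#' Describes the targeted panel: one row per amplicon (chromosome, start,
#' end; 1-based inclusive coordinates) and one row per variant (host
#' amplicon, position). Every variant must reference a known amplicon.
#'
#' @param amplicons data.frame with columns `amplicon_id`, `chrom`, `start`,
#'   `end`.
#' @param variants data.frame with columns `variant_id`, `amplicon_id`,
#'   `pos`; may have zero rows (depth-only panels).
#' @return an object of class `amplicon_panel`.
#' @export
amplicon_panel <- function(amplicons, variants = NULL) {
  amplicons <- as.data.frame(amplicons, stringsAsFactors = FALSE)
  need <- c("amplicon_id", "chrom", "start", "end")
  if (!all(need %in% names(amplicons))) {
    stop_load("panel needs columns: %s", paste(need, collapse = ", "))
  }
  amplicons$amplicon_id <- as.character(amplicons$amplicon_id)
  amplicons$chrom <- as.character(amplicons$chrom)
  amplicons$start <- as.integer(amplicons$start)
  amplicons$end <- as.integer(amplicons$end)
  if (anyDuplicated(amplicons$amplicon_id)) {
    stop_load("duplicate amplicon id in panel: %s",
              amplicons$amplicon_id[duplicated(amplicons$amplicon_id)][1L])
  }
  if (is.null(variants)) {
    variants <- data.frame(variant_id = character(), amplicon_id = character(),
                           pos = integer(), stringsAsFactors = FALSE)
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  needv <- c("variant_id", "amplicon_id", "pos")
  if (!all(needv %in% names(variants))) {
    stop_load("variant table needs columns: %s", paste(needv, collapse = ", "))
  }
  variants$variant_id <- as.character(variants$variant_id)
  variants$amplicon_id <- as.character(variants$amplicon_id)
  variants$pos <- as.integer(variants$pos)
  if (anyDuplicated(variants$variant_id)) {
    stop_load("duplicate variant id: %s",
              variants$variant_id[duplicated(variants$variant_id)][1L])
  }
  unknown <- setdiff(variants$amplicon_id, amplicons$amplicon_id)
  if (length(unknown)) {
    stop_load("variant references unknown amplicon '%s'", unknown[1L])
  }
  structure(list(amplicons = amplicons, variants = variants),
            class = "amplicon_panel")
}

#' Sort a panel into genome order
#'
#' Orders amplicons by chromosome (natural order: 1..22, X, Y) and start
#' position. Reading functions preserve file order; callers sort explicitly.
#'
#' @param panel an `amplicon_panel`.
#' @return the panel with amplicons reordered.
#' @export
sort_panel <- function(panel) {
  stopifnot(inherits(panel, "amplicon_panel"))
  lev <- chrom_order(panel$amplicons$chrom)
  ord <- order(match(panel$amplicons$chrom, lev), panel$amplicons$start)
  panel$amplicons <- panel$amplicons[ord, , drop = FALSE]
  rownames(panel$amplicons) <- NULL
  panel
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("Amplicon panel: %d amplicons on %d chromosomes, %d variants\n",
              nrow(x$amplicons), length(unique(x$amplicons$chrom)),
              nrow(x$variants)))
  invisible(x)
}

#' Construct a reference specification
#'
#' Names the reference cells (cells of known karyotype used to learn
#' baselines and noise parameters) and the per-chromosome copy-number
#' template of those cells. Chromosomes absent from `reference_cn` are
#' assumed diploid (copy number 2), so a near-diploid reference with e.g.
#' a known trisomy 10 is encoded as `reference_cn = c("10" = 3)`.
#'
#' @param reference_cells character vector of cell ids, non-empty.
#' @param reference_cn named integer vector, chromosome -> copy number in
#'   1..5; may be empty (all diploid).
#' @return an object of class `reference_spec`.
#' @export
reference_spec <- function(reference_cells, reference_cn = integer()) {
  reference_cells <- as.character(reference_cells)
  if (!length(reference_cells)) stop_load("reference cell list is empty")
  if (length(reference_cn)) {
    reference_cn <- structure(as.integer(reference_cn),
                              names = as.character(names(reference_cn)))
    if (any(is.na(reference_cn)) || any(reference_cn < 1 | reference_cn > 5)) {
      stop_load("reference copy numbers must be integers in 1..5")
    }
  } else {
    reference_cn <- structure(integer(), names = character())
  }
  structure(list(reference_cells = reference_cells,
                 reference_cn = reference_cn),
            class = "reference_spec")
}

# Template copy number for one chromosome under a reference spec
reference_cn_for <- function(spec, chrom) {
  cn <- spec$reference_cn[as.character(chrom)]
  ifelse(is.na(cn), 2L, cn)
}

#' Construct a call set
#'
#' Integer copy-number calls (states 1..5), cells as rows and chromosomes as
#' columns. Optionally carries amplicon-level state paths as an attribute.
#'
#' @param calls integer matrix, cells x chromosomes, entries in 1..5.
#' @param paths optional cell x amplicon integer matrix of per-amplicon
#'   states.
#' @return validated matrix of class `callset`.
#' @export
callset <- function(calls, paths = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop_load("call set requires cell row names and chromosome column names")
  }
  if (anyNA(calls) || any(calls < 1L | calls > 5L)) {
    stop_load("calls must be integers in 1..5")
  }
  structure(calls, paths = paths, class = c("callset", class(calls)))
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("Copy-number call set: %d cells x %d chromosomes\n",
              nrow(x), ncol(x)))
  tab <- table(factor(unclass(x), levels = 1:5))
  cat("State counts:", paste(sprintf("CN%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
  invisible(x)
}
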