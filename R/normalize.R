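#' Identify good barcodes
#'
#' A cell passes the barcode filter when its total read count exceeds 10%
#' (`fraction`) of the 11th-largest cell total. The rank-11 anchor makes the
#' threshold robust to a handful of jackpot barcodes while discarding debris
#' barcodes with few reads. With fewer than 11 cells the anchor falls back
#' to the smallest total, which keeps every cell.
#'
#' @param raw raw count matrix (amplicons x cells).
#' @param fraction threshold as a fraction of the rank-11 total (default
#'   0.10).
#' @return character vector of retained cell ids.
#' @export
good_barcodes <- function(raw, fraction = 0.10) {
  totals <- colSums(raw)
  if (all(totals == 0)) {
    warning("all cells have zero total counts; no good barcodes")
    return(character())
  }
  anchor <- if (length(totals) >= 11L) {
    sort(totals, decreasing = TRUE)[11L]
  } else {
    min(totals)
  }
  colnames(raw)[totals > fraction * anchor]
}

#' Depth- and amplicon-normalize raw counts (mb scheme)
#'
#' Three steps: (1) keep good barcodes via [good_barcodes()]; (2) adjust
#' for cell depth, dividing each cell's counts by its mean count plus a
#' stabilizer of 1; (3) scale each amplicon so the good-barcode median maps
#' to the diploid value 2:
#' \deqn{\tilde d_{i,c} = d_{i,c} / (\bar d_c + 1), \quad
#'       y_{i,c} = 2\,\tilde d_{i,c} / (m_i + 0.05)}
#' where \eqn{m_i} is the median of \eqn{\tilde d_{i,c}} over good barcodes.
#' Amplicons whose median \eqn{m_i} falls below `min_amplicon_median` carry
#' essentially no signal and are flagged for exclusion downstream.
#'
#' @param raw raw count matrix.
#' @param min_amplicon_median flag threshold on \eqn{m_i} (default 0.01).
#' @param good_barcode_fraction passed to [good_barcodes()].
#' @return list of class `mb_norm` with elements `normalized` (y, all
#'   cells), `good_barcodes`, `amplicon_median` (m), and `flagged`
#'   (logical per amplicon).
#' @export
mb_normalize <- function(raw, min_amplicon_median = 0.01,
                         good_barcode_fraction = 0.10) {
  good <- good_barcodes(raw, good_barcode_fraction)
  dbar <- colMeans(raw)
  dtil <- sweep(raw, 2L, dbar + 1, "/")
  m <- apply(dtil[, good, drop = FALSE], 1L, stats::median)
  y <- sweep(dtil, 1L, m + 0.05, "/") * 2
  structure(list(normalized = y,
                 good_barcodes = good,
                 amplicon_median = m,
                 flagged = m < min_amplicon_median),
            class = "mb_norm")
}

#' @export
print.mb_norm <- function(x, ...) {
  cat(sprintf(
    "mb-normalized counts: %d amplicons x %d cells (%d good barcodes, %d amplicons flagged)\n",
    nrow(x$normalized), ncol(x$normalized), length(x$good_barcodes),
    sum(x$flagged)))
  invisible(x)
}

#' Learn per-amplicon baselines from reference cells
#'
#' For each amplicon the baseline is the median normalized value over
#' reference cells, rescaled by the reference template so that a cell at
#' the template copy number maps to CN/2 after division:
#' \deqn{\beta_i = \mathrm{median}_{c \in R}(y_{i,c}) \cdot 2 / CN_{ref,i}}
#' A trisomic reference chromosome (template 3) therefore still yields a
#' baseline on the diploid scale. Amplicons with a zero baseline are
#' dropped with a warning.
#'
#' @param norm normalized count matrix (y from [mb_normalize()]).
#' @param spec a [reference_spec()].
#' @param panel an `amplicon_panel` giving each amplicon's chromosome.
#' @return named numeric vector of baselines; zero-baseline amplicons are
#'   absent.
#' @export
reference_baselines <- function(norm, spec, panel) {
  ref <- intersect(spec$reference_cells, colnames(norm))
  if (!length(ref)) stop_load("no reference cells present in the matrix")
  amp <- rownames(norm)
  chrom <- panel$amplicons$chrom[match(amp, panel$amplicons$amplicon_id)]
  if (anyNA(chrom)) {
    stop_load("amplicon '%s' missing from panel", amp[is.na(chrom)][1L])
  }
  cn_ref <- reference_cn_for(spec, chrom)
  med <- apply(norm[, ref, drop = FALSE], 1L, stats::median)
  beta <- med * 2 / cn_ref
  if (any(beta == 0)) {
    warning(sprintf("dropping %d amplicon(s) with zero reference baseline",
                    sum(beta == 0)))
    beta <- beta[beta > 0]
  }
  beta
}

#' Normalize depth against reference baselines
#'
#' Divides normalized counts by per-amplicon baselines, so a diploid cell
#' sits near 1 and a cell with copy number k near k/2. Amplicons without a
#' baseline are dropped.
#'
#' @param norm normalized count matrix.
#' @param baselines vector from [reference_baselines()].
#' @return depth-normalized matrix (rows restricted to baselined amplicons).
#' @export
depth_normalize <- function(norm, baselines) {
  keep <- intersect(rownames(norm), names(baselines))
  sweep(norm[keep, , drop = FALSE], 1L, baselines[keep], "/")
}
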