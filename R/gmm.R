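#' Fit per-probe Weibull distributions on reference cells
#'
#' Maximum-likelihood Weibull fit to each amplicon's normalized counts in
#' reference cells. Zero values are offset by a small constant before
#' fitting (the Weibull support excludes 0). Amplicons whose fit fails
#' (e.g. constant values) are flagged and excluded from synthesis.
#'
#' @param norm normalized count matrix.
#' @param spec a `reference_spec`.
#' @param min_reference_cells minimum reference cells required.
#' @param zero_offset replacement value for zeros.
#' @return data.frame with columns `amplicon_id`, `shape`, `scale`, `ok`.
#' @export
fit_probe_weibulls <- function(norm, spec, min_reference_cells = 5L,
                               zero_offset = 1e-3) {
  ref <- intersect(spec$reference_cells, colnames(norm))
  if (length(ref) < min_reference_cells) {
    stop_load("need at least %d reference cells, have %d",
              min_reference_cells, length(ref))
  }
  vals <- norm[, ref, drop = FALSE]
  out <- data.frame(amplicon_id = rownames(norm),
                    shape = NA_real_, scale = NA_real_, ok = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(vals))) {
    x <- vals[i, ]
    x[x <= 0] <- zero_offset
    fit <- tryCatch(
      fitdistrplus::fitdist(as.numeric(x), "weibull"),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$estimate)) &&
        all(fit$estimate > 0)) {
      out$shape[i] <- fit$estimate[["shape"]]
      out$scale[i] <- fit$estimate[["scale"]]
      out$ok[i] <- TRUE
    }
  }
  if (!all(out$ok)) {
    warning(sprintf("Weibull fit failed for %d amplicon(s); excluded",
                    sum(!out$ok)))
  }
  out
}

#' Generate synthetic cells at a copy-number state
#'
#' Draws per-probe values from the fitted Weibull distributions with the
#' scale parameter multiplied by k / CN_ref, so the synthetic population's
#' expected depth scales with the target copy number.
#'
#' @param weibulls data.frame from [fit_probe_weibulls()] (failed fits are
#'   skipped).
#' @param k target copy-number state.
#' @param n_syn number of synthetic cells.
#' @param cn_ref reference copy number per amplicon (scalar or vector on
#'   the retained amplicons).
#' @return matrix amplicons x synthetic cells.
#' @export
synthesize_cells <- function(weibulls, k, n_syn = 500L, cn_ref = 2) {
  wb <- weibulls[weibulls$ok, , drop = FALSE]
  if (length(cn_ref) == 1L) cn_ref <- rep(cn_ref, nrow(wb))
  m <- matrix(0, nrow(wb), n_syn,
              dimnames = list(wb$amplicon_id,
                              paste0("syn", k, "_", seq_len(n_syn))))
  for (i in seq_len(nrow(wb))) {
    m[i, ] <- stats::rweibull(n_syn, shape = wb$shape[i],
                              scale = wb$scale[i] * k / cn_ref[i])
  }
  m
}

#' Fit per-chromosome Gaussian components from synthetic cells
#'
#' Summarizes each synthetic cell to its per-chromosome median across
#' probes and fits one Gaussian per copy-number state by moment matching
#' (each component's members are known by construction, so no mixture EM
#' is needed).
#'
#' @param syn_list list of synthetic matrices indexed by state k.
#' @param chrom chromosome label per retained amplicon.
#' @return list of class `segment_gmm`: per chromosome, a data.frame with
#'   columns `k`, `mean`, `sd`.
#' @export
fit_segment_gmm <- function(syn_list, chrom) {
  chroms <- chrom_order(chrom)
  comp <- lapply(chroms, function(ch) {
    rows <- chrom == ch
    do.call(rbind, lapply(seq_along(syn_list), function(k) {
      med <- apply(syn_list[[k]][rows, , drop = FALSE], 2L, stats::median)
      data.frame(k = k, mean = mean(med), sd = max(stats::sd(med), 1e-6))
    }))
  })
  names(comp) <- chroms
  structure(comp, class = "segment_gmm")
}

#' Classify segment medians under the Gaussian mixture
#'
#' Assigns each cell's per-chromosome median to the state with the highest
#' posterior probability under equal priors; ties break toward the lower
#' state.
#'
#' @param seg_medians cells x chromosomes matrix of per-chromosome probe
#'   medians.
#' @param gmm a `segment_gmm`.
#' @return a `callset`.
#' @export
classify_segments <- function(seg_medians, gmm) {
  chroms <- intersect(names(gmm), colnames(seg_medians))
  calls <- matrix(NA_integer_, nrow(seg_medians), length(chroms),
                  dimnames = list(rownames(seg_medians), chroms))
  for (ch in chroms) {
    cm <- gmm[[ch]]
    dens <- vapply(seq_len(nrow(cm)), function(j) {
      stats::dnorm(seg_medians[, ch], cm$mean[j], cm$sd[j], log = TRUE)
    }, numeric(nrow(seg_medians)))
    dens <- matrix(dens, nrow = nrow(seg_medians))
    calls[, ch] <- cm$k[max.col(dens, ties.method = "first")]
  }
  callset(calls)
}

#' Call single-cell copy number with the depth-only Weibull/GMM baseline
#'
#' Re-implementation of the karyotapR-style caller: mb-normalize counts,
#' fit per-probe Weibull distributions on reference cells, generate
#' synthetic cells for each copy-number state 1..5 by scale multiplication,
#' summarize probes to whole-chromosome medians, fit Gaussian components
#' per state by moment matching, and classify real cells by posterior
#' probability under equal priors. BAF is not used.
#'
#' @param counts raw count matrix.
#' @param panel an `amplicon_panel`.
#' @param reference a `reference_spec`.
#' @param n_syn synthetic cells per state.
#' @param states number of copy-number states.
#' @param control list from [hmm_control()] (only the normalization
#'   settings are used).
#' @return object of class `cnv_gmm_fit` with `calls`, `weibulls`, `gmm`,
#'   `panel`.
#' @export
call_cnv_gmm <- function(counts, panel, reference, n_syn = 500L,
                         states = 5L, control = hmm_control()) {
  stopifnot(inherits(panel, "amplicon_panel"),
            inherits(reference, "reference_spec"))
  panel <- sort_panel(panel)
  norm <- mb_normalize(counts,
                       min_amplicon_median = control$min_amplicon_median,
                       good_barcode_fraction = control$good_barcode_fraction)
  cells <- norm$good_barcodes
  keep_amp <- intersect(panel$amplicons$amplicon_id,
                        rownames(counts)[!norm$flagged])
  y <- norm$normalized[keep_amp, cells, drop = FALSE]
  chrom_all <- panel$amplicons$chrom[
    match(keep_amp, panel$amplicons$amplicon_id)]
  wb <- fit_probe_weibulls(y, reference)
  ok_ids <- wb$amplicon_id[wb$ok]
  chrom <- chrom_all[match(ok_ids, keep_amp)]
  cn_ref <- reference_cn_for(reference, chrom)
  syn <- lapply(seq_len(states), function(k) {
    synthesize_cells(wb, k, n_syn = n_syn, cn_ref = cn_ref)
  })
  gmm <- fit_segment_gmm(syn, chrom)
  chroms <- names(gmm)
  seg <- matrix(NA_real_, length(cells), length(chroms),
                dimnames = list(cells, chroms))
  yk <- y[ok_ids, , drop = FALSE]
  for (ch in chroms) {
    seg[, ch] <- apply(yk[chrom == ch, , drop = FALSE], 2L, stats::median)
  }
  calls <- classify_segments(seg, gmm)
  structure(list(calls = calls, weibulls = wb, gmm = gmm,
                 segment_medians = seg, panel = panel,
                 chromosomes = chroms),
            class = "cnv_gmm_fit")
}

#' @export
print.cnv_gmm_fit <- function(x, ...) {
  cat("Depth-only Weibull/GMM copy-number fit\n")
  cat(sprintf("  %d cells x %d chromosomes (%d probes fitted)\n",
              nrow(x$calls), ncol(x$calls), sum(x$weibulls$ok)))
  invisible(x)
}

#' @export
summary.cnv_gmm_fit <- function(object, ...) {
  calls <- unclass(object$calls)
  tab <- table(factor(calls, levels = 1:5))
  ans <- list(n_cells = nrow(calls), n_chrom = ncol(calls),
              state_freq = tab / sum(tab),
              altered_fraction = mean(calls != 2L),
              median_shape = stats::median(object$weibulls$shape,
                                           na.rm = TRUE))
  class(ans) <- "summary.cnv_gmm_fit"
  ans
}

#' @export
print.summary.cnv_gmm_fit <- function(x, ...) {
  cat(sprintf("GMM copy-number calls for %d cells x %d chromosomes\n",
              x$n_cells, x$n_chrom))
  cat("State frequencies:\n")
  print(round(x$state_freq, 3))
  cat(sprintf("Altered (CN != 2) fraction: %.3f\n", x$altered_fraction))
  invisible(x)
}

#' @export
coef.cnv_gmm_fit <- function(object, ...) {
  object$weibulls
}

#' @rdname plot.cnv_hmm_fit
#' @export
plot.cnv_gmm_fit <- function(x, ...) {
  plot_callset(x$calls, main = "GMM copy-number calls", ...)
}
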