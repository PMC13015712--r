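#' Control parameters for the HMM caller
#'
#' @param states number of copy-number states (states 1..K).
#' @param max_iter maximum Baum-Welch iterations per cell.
#' @param tol EM convergence tolerance on parameter change.
#' @param epsilon initial state-switch probability.
#' @param w0 scale of the depth-mean ridge toward the prior means k/2,
#'   in units of depth observations per state; see [baum_welch()].
#' @param eps_prior strength of the switch-rate prior; see [baum_welch()].
#' @param het_threshold MAF above which a reference observation is counted
#'   heterozygous when estimating per-amplicon heterozygosity (midway
#'   between the homozygous expectation 0 and the diploid heterozygous
#'   expectation 0.5, minus a noise margin).
#' @param min_amplicon_median amplicons whose good-barcode median
#'   normalized count falls below this are excluded.
#' @param good_barcode_fraction barcode filter fraction, see
#'   [good_barcodes()].
#' @param max_dispersion_mult probe QC: amplicons whose reference-cell
#'   mean squared depth residual exceeds this multiple of the median
#'   amplicon residual are excluded. Such probes (typically very
#'   heavy-tailed capture distributions) would otherwise dominate the
#'   pooled depth variance and drown the depth signal of well-behaved
#'   probes. Set to `Inf` to disable.
#' @return list of control values.
#' @export
hmm_control <- function(states = 5L, max_iter = 50L, tol = 1e-5,
                        epsilon = 1e-3, w0 = 2, eps_prior = 20,
                        het_threshold = 0.15,
                        min_amplicon_median = 0.01,
                        good_barcode_fraction = 0.10,
                        max_dispersion_mult = 8) {
  list(states = as.integer(states), max_iter = as.integer(max_iter),
       tol = tol, epsilon = epsilon, w0 = w0, eps_prior = eps_prior,
       het_threshold = het_threshold,
       min_amplicon_median = min_amplicon_median,
       good_barcode_fraction = good_barcode_fraction,
       max_dispersion_mult = max_dispersion_mult)
}

#' Call single-cell copy number with the joint depth + BAF HMM
#'
#' Fits the per-chromosome hidden Markov model to every cell passing the
#' barcode filter. The pipeline: (1) mb-normalize raw counts and drop
#' near-zero-median amplicons; (2) learn per-amplicon depth baselines,
#' depth variance, MAF standard deviation, and per-amplicon heterozygosity
#' rates from the designated reference cells; (3) per cell, estimate state
#' means and noise parameters by Baum-Welch (chains per chromosome, pooled
#' M-step), decode the most probable state path by Viterbi, and (4)
#' aggregate amplicon states to one modal call per chromosome.
#'
#' @param counts raw count matrix (amplicons x cells).
#' @param baf BAF matrix (variants x cells); may be NULL for depth-only
#'   calling.
#' @param panel an `amplicon_panel`.
#' @param reference a `reference_spec`.
#' @param control list from [hmm_control()].
#' @return object of class `cnv_hmm_fit` with components `calls` (a
#'   `callset`), `paths` (cells x amplicons state matrix), `reference`
#'   (learned baselines and noise parameters), `cell_params` (per-cell
#'   fitted parameters and EM diagnostics), `panel`, and `control`.
#' @export
call_cnv_hmm <- function(counts, baf = NULL, panel, reference,
                         control = hmm_control()) {
  stopifnot(inherits(panel, "amplicon_panel"),
            inherits(reference, "reference_spec"))
  K <- control$states
  panel <- sort_panel(panel)
  norm <- mb_normalize(counts,
                       min_amplicon_median = control$min_amplicon_median,
                       good_barcode_fraction = control$good_barcode_fraction)
  cells <- norm$good_barcodes
  if (!length(cells)) stop("no cells pass the barcode filter")
  ref_cells <- intersect(reference$reference_cells, cells)
  if (!length(ref_cells)) stop("no reference cells pass the barcode filter")
  keep_amp <- intersect(panel$amplicons$amplicon_id,
                        rownames(counts)[!norm$flagged])
  if (sum(norm$flagged)) {
    warning(sprintf("excluding %d amplicon(s) with near-zero median counts",
                    sum(norm$flagged)))
  }
  y <- norm$normalized[keep_amp, cells, drop = FALSE]
  sub_panel <- panel
  sub_panel$amplicons <- panel$amplicons[
    panel$amplicons$amplicon_id %in% keep_amp, , drop = FALSE]
  beta <- reference_baselines(y, reference, sub_panel)
  dnorm_mat <- depth_normalize(y, beta)
  # probe QC: drop amplicons whose reference-cell depth dispersion is an
  # outlier relative to the panel (they carry no usable depth signal and
  # would inflate the pooled variance)
  amp_ids <- rownames(dnorm_mat)
  chrom <- sub_panel$amplicons$chrom[
    match(amp_ids, sub_panel$amplicons$amplicon_id)]
  cn_ref <- reference_cn_for(reference, chrom)
  mse <- rowMeans((dnorm_mat[, ref_cells, drop = FALSE] - cn_ref / 2)^2)
  noisy <- mse > control$max_dispersion_mult * stats::median(mse)
  if (any(noisy)) {
    warning(sprintf("excluding %d over-dispersed amplicon(s)", sum(noisy)))
    dnorm_mat <- dnorm_mat[!noisy, , drop = FALSE]
    amp_ids <- rownames(dnorm_mat)
    chrom <- chrom[!noisy]
    cn_ref <- cn_ref[!noisy]
    mse <- mse[!noisy]
  }
  sub_panel$amplicons <- sub_panel$amplicons[
    sub_panel$amplicons$amplicon_id %in% amp_ids, , drop = FALSE]
  chroms <- chrom_order(chrom)
  dropped_chr <- setdiff(chrom_order(panel$amplicons$chrom), chroms)
  if (length(dropped_chr)) {
    warning("no usable amplicons on chromosome(s): ",
            paste(dropped_chr, collapse = ", "), "; no calls emitted there")
  }
  # pooled reference depth variance about the template copy number
  sigma_d2 <- mean(mse)
  # fold BAF to minor allele frequencies; restrict to retained amplicons
  var_tab <- sub_panel$variants[
    sub_panel$variants$amplicon_id %in% amp_ids, , drop = FALSE]
  have_baf <- !is.null(baf) && nrow(var_tab) > 0L
  if (have_baf) {
    var_tab <- var_tab[var_tab$variant_id %in% rownames(baf), , drop = FALSE]
  }
  have_baf <- have_baf && nrow(var_tab) > 0L
  if (have_baf) {
    maf <- pmin(baf[var_tab$variant_id, cells, drop = FALSE],
                1 - baf[var_tab$variant_id, cells, drop = FALSE])
  }
  # per-amplicon heterozygosity and MAF noise from reference cells
  h <- numeric(length(amp_ids))
  sigma_b <- 0.1
  if (have_baf) {
    ref_maf <- maf[, ref_cells, drop = FALSE]
    # MAF spread about the nearest diploid genotype mean (0 or 0.5)
    r <- ref_maf - ifelse(ref_maf > 0.25, 0.5, 0)
    if (any(!is.na(r))) sigma_b <- max(sqrt(mean(r^2, na.rm = TRUE)), 1e-3)
    is_het <- ref_maf > control$het_threshold
    amp_of_var <- match(var_tab$amplicon_id, amp_ids)
    hets <- rowsum(rowSums(is_het, na.rm = TRUE), amp_of_var)
    obs_n <- rowsum(rowSums(!is.na(ref_maf)), amp_of_var)
    h_raw <- ifelse(obs_n > 0, hets / pmax(obs_n, 1L), 0)
    # debias: a homozygous observation exceeds the threshold with
    # probability p0 under the measured noise, so subtract the expected
    # false-heterozygous rate. BAF cannot drop below 0, so homozygous
    # noise is one-sided and its boundary atom at 0 halves the apparent
    # second moment: the unclamped noise scale is sigma_b * sqrt(2).
    p0 <- stats::pnorm(control$het_threshold, 0, sigma_b * sqrt(2),
                       lower.tail = FALSE)
    p0 <- min(p0, 0.5)
    h[as.integer(rownames(hets))] <- pmax(0, (h_raw - p0) / (1 - p0))
  }
  layout <- list(
    chains = split(seq_along(amp_ids),
                   factor(chrom, levels = chroms)),
    h = h,
    b_amp_all = if (have_baf) match(var_tab$amplicon_id, amp_ids) else integer()
  )
  params0 <- list(mu = seq_len(K) / 2, sigma_d2 = sigma_d2,
                  sigma_b = sigma_b, epsilon = control$epsilon, K = K)
  calls <- matrix(NA_integer_, length(cells), length(chroms),
                  dimnames = list(cells, chroms))
  paths <- matrix(NA_integer_, length(cells), length(amp_ids),
                  dimnames = list(cells, amp_ids))
  cell_params <- matrix(NA_real_, length(cells), K + 6L,
                        dimnames = list(cells,
                                        c(paste0("mu", seq_len(K)),
                                          "sigma_d2", "sigma_b", "epsilon",
                                          "loglik", "n_iter", "converged")))
  for (ci in seq_along(cells)) {
    d <- dnorm_mat[, ci]
    b_all <- if (have_baf) maf[, ci] else numeric()
    obs <- build_cell_obs_internal(d, b_all, layout)
    fit <- baum_welch(obs, params0, max_iter = control$max_iter,
                      tol = control$tol, w0 = control$w0,
                      eps_prior = control$eps_prior)
    Tm <- transition_matrix(fit$params$epsilon, K)
    logE <- emission_matrix(obs, fit$params$mu, fit$params$sigma_d2,
                            fit$params$sigma_b, maf_mixture_components(K))
    path <- integer(length(amp_ids))
    for (ch in seq_along(layout$chains)) {
      ii <- layout$chains[[ch]]
      path[ii] <- viterbi_path(logE[ii, , drop = FALSE], Tm)
    }
    paths[ci, ] <- path
    calls[ci, ] <- aggregate_segments(path, chrom)
    cell_params[ci, ] <- c(fit$params$mu, fit$params$sigma_d2,
                           fit$params$sigma_b, fit$params$epsilon,
                           fit$loglik[length(fit$loglik)], fit$n_iter,
                           as.numeric(fit$converged))
  }
  structure(list(
    calls = callset(calls, paths = paths),
    paths = paths,
    reference = list(baselines = beta, sigma_d2 = sigma_d2,
                     sigma_b = sigma_b, het_rates = h,
                     reference_cells = ref_cells),
    cell_params = cell_params,
    panel = sub_panel,
    chromosomes = chroms,
    control = control),
    class = "cnv_hmm_fit")
}

#' @export
print.cnv_hmm_fit <- function(x, ...) {
  cat("Joint depth + allele-frequency HMM copy-number fit\n")
  cat(sprintf("  %d cells x %d chromosomes (%d amplicons)\n",
              nrow(x$calls), ncol(x$calls), ncol(x$paths)))
  cat(sprintf("  reference: %d cells, sigma_d = %.3f, sigma_b = %.3f, mean het = %.2f\n",
              length(x$reference$reference_cells), sqrt(x$reference$sigma_d2),
              x$reference$sigma_b, mean(x$reference$het_rates)))
  cat(sprintf("  EM converged for %d/%d cells\n",
              sum(x$cell_params[, "converged"] == 1), nrow(x$calls)))
  invisible(x)
}

#' @export
summary.cnv_hmm_fit <- function(object, ...) {
  calls <- unclass(object$calls)
  tab <- table(factor(calls, levels = 1:5))
  ans <- list(
    n_cells = nrow(calls), n_chrom = ncol(calls),
    state_freq = tab / sum(tab),
    altered_fraction = mean(calls != 2L),
    mean_iters = mean(object$cell_params[, "n_iter"]),
    frac_converged = mean(object$cell_params[, "converged"]),
    reference = object$reference[c("sigma_d2", "sigma_b")])
  class(ans) <- "summary.cnv_hmm_fit"
  ans
}

#' @export
print.summary.cnv_hmm_fit <- function(x, ...) {
  cat(sprintf("HMM copy-number calls for %d cells x %d chromosomes\n",
              x$n_cells, x$n_chrom))
  cat("State frequencies:\n")
  print(round(x$state_freq, 3))
  cat(sprintf("Altered (CN != 2) fraction: %.3f\n", x$altered_fraction))
  cat(sprintf("Mean EM iterations %.1f (%.0f%% converged)\n",
              x$mean_iters, 100 * x$frac_converged))
  invisible(x)
}

#' @export
coef.cnv_hmm_fit <- function(object, ...) {
  object$cell_params[, c(paste0("mu", seq_len(object$control$states)),
                         "sigma_d2", "sigma_b", "epsilon"), drop = FALSE]
}

#' Heatmap of copy-number calls
#'
#' Cells as rows, chromosomes as columns, colored by called state
#' (blue = loss, white = diploid, red = gain).
#'
#' @param x a `cnv_hmm_fit` or `cnv_gmm_fit`.
#' @param ... passed to [graphics::image()].
#' @export
plot.cnv_hmm_fit <- function(x, ...) {
  plot_callset(x$calls, main = "HMM copy-number calls", ...)
}

plot_callset <- function(calls, main = "", ...) {
  m <- unclass(calls)
  cols <- c("#2166AC", "#92C5DE", "#FFFFFF", "#F4A582", "#B2182B")
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  col = cols, zlim = c(0.5, 5.5),
                  xlab = "chromosome", ylab = "cell", axes = FALSE,
                  main = main, ...)
  graphics::axis(1L, at = seq_len(ncol(m)), labels = colnames(m), las = 2)
  graphics::box()
  invisible(calls)
}
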