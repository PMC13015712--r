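#' Multi-class confusion matrix of copy-number calls
#'
#' Tabulates cell-by-chromosome pairs into a K x K matrix with true states
#' as rows and predicted states as columns. Calls and truth are aligned by
#' cell and chromosome names; a shape mismatch is an error.
#'
#' @param calls a `callset` (or integer matrix) of predictions.
#' @param truth a `callset` (or integer matrix) of true states.
#' @param K number of states.
#' @return K x K integer matrix, rows = true state, columns = predicted.
#' @export
cnv_confusion <- function(calls, truth, K = 5L) {
  calls <- unclass(calls)
  truth <- unclass(truth)
  common_cells <- intersect(rownames(truth), rownames(calls))
  common_chr <- intersect(colnames(truth), colnames(calls))
  if (!length(common_cells) || !length(common_chr)) {
    stop("calls and truth share no cells or chromosomes")
  }
  if (length(common_cells) != nrow(calls) ||
      length(common_chr) != ncol(calls)) {
    stop("calls and truth cover different cells x chromosomes")
  }
  p <- as.vector(calls[common_cells, common_chr])
  g <- as.vector(truth[common_cells, common_chr])
  m <- table(factor(g, levels = seq_len(K)),
             factor(p, levels = seq_len(K)))
  matrix(as.integer(m), K, K,
         dimnames = list(true = seq_len(K), predicted = seq_len(K)))
}

#' Metrics from a confusion matrix
#'
#' Computes accuracy (trace over total), per-class precision/recall/F1,
#' macro-F1 and balanced accuracy averaged over the classes present in
#' truth or predictions, per-class sensitivity for all K states, and the
#' binary alteration metrics obtained by collapsing states to altered
#' (CN != 2) versus diploid (CN = 2). All 0/0 ratios are defined as 0,
#' so an all-diploid predictor has zero alteration F1.
#'
#' @param cm confusion matrix from [cnv_confusion()].
#' @return list of class `cnv_metrics` with fields `accuracy`, `macro_f1`,
#'   `balanced_accuracy`, `per_class_sensitivity`,
#'   `alteration_sensitivity`, `alteration_precision`, `alteration_f1`,
#'   and `confusion`.
#' @export
cnv_metrics <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  K <- nrow(cm)
  tp <- diag(cm)
  rowt <- rowSums(cm)
  colt <- colSums(cm)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  prec <- safe_div(tp, colt)
  rec <- safe_div(tp, rowt)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  present <- which(rowt > 0 | colt > 0)
  # binary altered (CN != 2) vs diploid collapse
  alt <- setdiff(seq_len(K), 2L)
  TPa <- sum(cm[alt, alt])
  FNa <- sum(cm[alt, 2L])
  FPa <- sum(cm[2L, alt])
  sens_a <- safe_div(TPa, TPa + FNa)
  prec_a <- safe_div(TPa, TPa + FPa)
  structure(list(
    accuracy = sum(tp) / total,
    macro_f1 = mean(f1[present]),
    balanced_accuracy = mean(rec[present]),
    per_class_sensitivity = structure(rec, names = rownames(cm)),
    alteration_sensitivity = sens_a,
    alteration_precision = prec_a,
    alteration_f1 = safe_div(2 * prec_a * sens_a, prec_a + sens_a),
    confusion = cm), class = "cnv_metrics")
}

#' @export
print.cnv_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | macro-F1 %.3f | balanced acc %.3f | alteration F1 %.3f\n",
    x$accuracy, x$macro_f1, x$balanced_accuracy, x$alteration_f1))
  cat("per-class sensitivity:",
      paste(sprintf("CN%s=%.3f", names(x$per_class_sensitivity),
                    x$per_class_sensitivity), collapse = " "), "\n")
  invisible(x)
}

#' Naive diploid predictor
#'
#' Calls CN = 2 for every cell and chromosome; the performance floor for
#' alteration detection.
#'
#' @param truth a `callset` giving the cells and chromosomes to cover.
#' @return a `callset` of all-diploid calls.
#' @export
naive_baseline <- function(truth) {
  m <- unclass(truth)
  m[] <- 2L
  callset(m)
}

#' Run simulation, callers, and metrics over replicates
#'
#' Orchestrates one experimental condition: simulates `replicates`
#' datasets, runs the requested methods (joint HMM, depth-only GMM, naive
#' diploid) on each, and tabulates the evaluation metrics.
#'
#' @param study 1 or 2.
#' @param direction "gain" or "loss" (study 2).
#' @param methods subset of c("hmm", "gmm", "naive").
#' @param replicates number of replicates.
#' @param seed master seed; replicate seeds are derived deterministically.
#' @param sim_args named list of overrides passed to the study builder.
#' @param control HMM control list.
#' @param label condition label recorded in the output.
#' @return data.frame, one row per replicate x method, with metric columns.
#' @export
benchmark_condition <- function(study = 2L, direction = "gain",
                                methods = c("hmm", "gmm", "naive"),
                                replicates = 3L, seed = 1L,
                                sim_args = list(),
                                control = hmm_control(),
                                label = "") {
  rows <- list()
  for (r in seq_len(replicates)) {
    rseed <- derive_seed(seed, sprintf("study%d/%s/%s/rep%d",
                                       study, direction, label, r))
    sim <- if (study == 1L) {
      do.call(build_study1, c(list(seed = rseed), sim_args))
    } else {
      do.call(build_study2, c(list(direction = direction, seed = rseed),
                              sim_args))
    }
    calls <- list()
    if ("hmm" %in% methods) {
      fit <- call_cnv_hmm(sim$counts, sim$baf, sim$panel, sim$reference,
                          control = control)
      calls$hmm <- fit$calls
    }
    if ("gmm" %in% methods) {
      fit <- call_cnv_gmm(sim$counts, sim$panel, sim$reference,
                          control = control)
      calls$gmm <- fit$calls
    }
    if ("naive" %in% methods) calls$naive <- naive_baseline(sim$truth)
    for (meth in names(calls)) {
      truth_sub <- unclass(sim$truth)[rownames(calls[[meth]]),
                                      colnames(calls[[meth]]), drop = FALSE]
      met <- cnv_metrics(cnv_confusion(calls[[meth]], truth_sub))
      rows[[length(rows) + 1L]] <- data.frame(
        label = label, study = study, direction = direction,
        replicate = r, method = meth,
        accuracy = met$accuracy, macro_f1 = met$macro_f1,
        balanced_accuracy = met$balanced_accuracy,
        alteration_f1 = met$alteration_f1,
        alteration_sensitivity = met$alteration_sensitivity,
        sens_cn1 = met$per_class_sensitivity[[1L]],
        sens_cn2 = met$per_class_sensitivity[[2L]],
        sens_cn3 = met$per_class_sensitivity[[3L]],
        sens_cn4 = met$per_class_sensitivity[[4L]],
        sens_cn5 = met$per_class_sensitivity[[5L]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate benchmark rows to condition means and sds
#'
#' @param results data.frame from [benchmark_condition()] (possibly
#'   row-bound across conditions).
#' @return data.frame of per-condition, per-method means and sds.
#' @export
benchmark_summary <- function(results) {
  metric_cols <- setdiff(names(results),
                         c("label", "study", "direction", "replicate",
                           "method"))
  key <- interaction(results$label, results$direction, results$method,
                     drop = TRUE)
  out <- lapply(split(results, key), function(d) {
    means <- vapply(d[metric_cols], mean, numeric(1))
    sds <- vapply(d[metric_cols], stats::sd, numeric(1))
    cbind(d[1L, c("label", "study", "direction", "method")],
          as.data.frame(as.list(means)),
          structure(as.data.frame(as.list(sds)),
                    names = paste0(metric_cols, "_sd")))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
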