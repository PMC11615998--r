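# Ranking audiometric frequency combinations by how well the demographic /
# lifestyle risk-factor model predicts the hearing outcome defined on each
# combination. The set on which the risk factors carry the most signal is
# the most reliable phenotype definition for susceptibility screening.

#' Default frequency sets evaluated by the protocol
#' @export
NIHL_DEFAULT_FREQ_SETS <- list(
  4, 12.5, c(4, 12.5), c(4, 6, 12.5), c(4, 10, 12.5),
  c(4, 6, 10, 12.5), c(3, 4, 6, 10, 12.5))

#' Evaluate candidate frequency sets
#'
#' For each set, the hearing-outcome label is rebuilt via the spec's label
#' rule over that set and [cross_validated_fit()] is run with the same fold
#' seed, so ranking differences reflect the label, not fold noise (folds
#' are stratified by label, so partitions coincide exactly whenever two
#' sets induce the same labels). Reported `mean_auc`/`mean_accuracy` are
#' unweighted means over the algorithms' fold-mean metrics; the sds are
#' across algorithms. A set whose label is degenerate (single class) is
#' reported as failed without affecting the others.
#'
#' @param x a [cohort()].
#' @param freq_sets list of numeric frequency vectors (kHz).
#' @param spec a [diagnostic_model_spec()]; its label-rule frequencies are
#'   replaced per set.
#' @return data.frame with one row per set: `freq_set` (label string),
#'   `mean_auc`, `sd_auc`, `mean_accuracy`, `sd_accuracy`, `ok`, plus a
#'   `per_algorithm` list-column.
#' @export
evaluate_frequency_sets <- function(x, freq_sets = NIHL_DEFAULT_FREQ_SETS,
                                    spec = diagnostic_model_spec()) {
  stopifnot(length(freq_sets) > 0)
  grid <- cohort_frequencies(x)
  rows <- lapply(freq_sets, function(fs) {
    bad <- setdiff(fs, grid)
    if (length(bad) > 0)
      stop("frequency not on the grid: ", paste(bad, collapse = ", "))
    sp <- spec
    sp$label_rule$frequencies <- fs
    res <- tryCatch(cross_validated_fit(x, sp), error = function(e) e)
    if (inherits(res, "error")) {
      return(data.frame(freq_set = paste(fs, collapse = "+"),
                        n_freqs = length(fs),
                        mean_auc = NA_real_, sd_auc = NA_real_,
                        mean_accuracy = NA_real_, sd_accuracy = NA_real_,
                        ok = FALSE))
    }
    pa <- res$per_algorithm
    out <- data.frame(freq_set = paste(fs, collapse = "+"),
                      n_freqs = length(fs),
                      mean_auc = mean(pa$mean_auc),
                      sd_auc = sd(pa$mean_auc),
                      mean_accuracy = mean(pa$mean_accuracy),
                      sd_accuracy = sd(pa$mean_accuracy),
                      ok = TRUE)
    out$per_algorithm <- list(pa)
    out
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$per_algorithm)) r$per_algorithm <- list(NULL)
    r
  }))
  rownames(out) <- NULL
  out
}

#' Rank evaluated frequency sets
#'
#' Sort by mean AUC descending, ties by mean accuracy descending, then by
#' smaller set size. Failed sets sink to the bottom.
#'
#' @param results output of [evaluate_frequency_sets()].
#' @return the same data.frame, reordered.
#' @export
rank_frequency_sets <- function(results) {
  stopifnot(nrow(results) > 0)
  auc <- ifelse(results$ok, results$mean_auc, -Inf)
  acc <- ifelse(results$ok, results$mean_accuracy, -Inf)
  out <- results[order(-auc, -acc, results$n_freqs), , drop = FALSE]
  rownames(out) <- NULL
  out
}
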