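# Method 6: train risk-factor classifiers of the hearing outcome, then
# select extreme individuals among the subjects misclassified by ALL
# algorithms on out-of-fold predictions. A subject whose hearing is worse
# than every model predicts from age/sex/CNE/lifestyle is a susceptibility
# candidate; one whose hearing is better than predicted is a resistance
# candidate.

#' Binarization rule for the hearing outcome
#'
#' The source studies never state how "hearing outcome" was binarized; the
#' package default declares a case when the bilateral mean HT over the
#' configured frequency set exceeds 25 dB HL, the same normal-hearing bound
#' the study-level screening uses.
#'
#' @param frequencies phenotype frequency set (kHz).
#' @param ears `"left"`, `"right"` or `"bilateral"`.
#' @param threshold dB HL cutoff (case if mean HT > threshold).
#' @return a `nihl_label_rule`.
#' @export
label_rule <- function(frequencies = c(4, 12.5), ears = "bilateral",
                       threshold = 25) {
  stopifnot(length(frequencies) > 0, is.finite(threshold))
  structure(list(frequencies = frequencies, ears = ears,
                 threshold = threshold), class = "nihl_label_rule")
}

apply_label_rule <- function(x, rule) {
  as.integer(phenotype_ht(x, rule$frequencies, rule$ears) > rule$threshold)
}

#' Diagnostic model specification
#'
#' @param features subset of `age`, `sex`, `cne`, `smoking`, `drinking`.
#' @param label_rule a [label_rule()].
#' @param algorithms subset of `adaboost`, `mlp`, `random_forest`, `svm`.
#' @param k_folds number of cross-validation folds (>= 2).
#' @param seed RNG seed controlling folds and algorithm initialization.
#' @param include_phenotype experimental: if TRUE, appends the mean HT of
#'   the label-rule frequency set to the features. This makes the target
#'   partially circular and is off by default; kept only for comparison
#'   with the alternate reading of the protocol.
#' @return a `nihl_model_spec`.
#' @export
diagnostic_model_spec <- function(features = c("age", "sex", "cne",
                                               "smoking", "drinking"),
                                  label_rule = nihlscreen::label_rule(),
                                  algorithms = NIHL_ALGORITHMS,
                                  k_folds = 10L, seed = 1L,
                                  include_phenotype = FALSE) {
  stopifnot(length(features) > 0, length(algorithms) > 0, k_folds >= 2,
            all(features %in% c("age", "sex", "cne", "smoking", "drinking")),
            all(algorithms %in% NIHL_ALGORITHMS),
            inherits(label_rule, "nihl_label_rule"))
  structure(list(features = features, label_rule = label_rule,
                 algorithms = algorithms, k_folds = as.integer(k_folds),
                 seed = as.integer(seed),
                 include_phenotype = include_phenotype),
            class = "nihl_model_spec")
}

# Raw (unstandardized) feature matrix: categoricals as 0/1 indicators.
feature_matrix <- function(x, spec) {
  cols <- list(age = x$age,
               sex = as.numeric(x$sex == "male"),
               cne = x$cne,
               smoking = as.numeric(x$smoking == "currently"),
               drinking = as.numeric(x$drinking == "currently"))
  X <- do.call(cbind, cols[spec$features])
  colnames(X) <- spec$features
  if (isTRUE(spec$include_phenotype))
    X <- cbind(X, phenotype = phenotype_ht(
      x, spec$label_rule$frequencies, spec$label_rule$ears))
  X
}

NIHL_CONTINUOUS_FEATURES <- c("age", "cne", "phenotype")

# Standardize continuous columns by TRAINING-fold statistics only.
standardize_fold <- function(X_train, X_test) {
  for (cn in intersect(colnames(X_train), NIHL_CONTINUOUS_FEATURES)) {
    mu <- mean(X_train[, cn])
    s <- sd(X_train[, cn])
    if (s == 0) s <- 1
    X_train[, cn] <- (X_train[, cn] - mu) / s
    X_test[, cn] <- (X_test[, cn] - mu) / s
  }
  list(train = X_train, test = X_test)
}

# Rank-based AUC (equivalent to the Mann-Whitney statistic), midrank ties.
auc_score <- function(prob, truth) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated fit of the diagnostic model
#'
#' Stratified k-fold cross-validation seeded by `spec$seed`. Every subject
#' receives exactly one out-of-fold prediction per algorithm; continuous
#' features are standardized with training-fold statistics only. Per-fold
#' accuracy and AUC are aggregated to mean and sd per algorithm.
#'
#' @param x a [cohort()].
#' @param spec a [diagnostic_model_spec()].
#' @return a `nihl_model_eval`: `per_algorithm` (data.frame of mean/sd
#'   accuracy and AUC), `pooled` (unweighted mean over algorithms),
#'   `per_subject` (id, true label, out-of-fold predicted label and
#'   case-probability per algorithm).
#' @export
cross_validated_fit <- function(x, spec) {
  stopifnot(inherits(x, "nihl_cohort"), inherits(spec, "nihl_model_spec"))
  y <- apply_label_rule(x, spec$label_rule)
  if (length(unique(y)) < 2)
    stop("label rule yields a single class")
  if (min(table(y)) < spec$k_folds)
    stop("a class has fewer members than k_folds")
  X <- feature_matrix(x, spec)
  n <- nrow(X)
  k <- spec$k_folds

  set.seed(spec$seed)
  fold <- stratified_folds(y, k)

  prob <- matrix(NA_real_, n, length(spec$algorithms),
                 dimnames = list(NULL, spec$algorithms))
  fold_acc <- fold_auc <- matrix(
    NA_real_, k, length(spec$algorithms),
    dimnames = list(NULL, spec$algorithms))

  for (f in seq_len(k)) {
    test <- fold == f
    Z <- standardize_fold(X[!test, , drop = FALSE],
                          X[test, , drop = FALSE])
    for (alg in spec$algorithms) {
      # per-(fold, algorithm) substream so stages are independently rerunnable
      set.seed(spec$seed + 131L * f + 17L * match(alg, NIHL_ALGORITHMS))
      fit <- ml_fit(alg, Z$train, y[!test])
      p <- ml_predict_prob(fit, Z$test)
      prob[test, alg] <- p
      fold_acc[f, alg] <- mean((p > 0.5) == (y[test] == 1))
      fold_auc[f, alg] <- auc_score(p, y[test])
    }
  }

  per_algorithm <- data.frame(
    algorithm = spec$algorithms,
    mean_accuracy = colMeans(fold_acc),
    sd_accuracy = apply(fold_acc, 2, sd),
    mean_auc = colMeans(fold_auc),
    sd_auc = apply(fold_auc, 2, sd),
    row.names = NULL)

  per_subject <- data.frame(id = x$id, true = y)
  for (alg in spec$algorithms) {
    per_subject[[paste0("pred_", alg)]] <- as.integer(prob[, alg] > 0.5)
    per_subject[[paste0("prob_case_", alg)]] <- prob[, alg]
  }

  structure(list(per_algorithm = per_algorithm,
                 pooled = c(mean_accuracy = mean(per_algorithm$mean_accuracy),
                            mean_auc = mean(per_algorithm$mean_auc)),
                 per_subject = per_subject,
                 spec = spec),
            class = "nihl_model_eval")
}

#' @export
print.nihl_model_eval <- function(x, ...) {
  cat(sprintf("<model eval> pooled accuracy %.3f, AUC %.3f (%d-fold CV)\n",
              x$pooled["mean_accuracy"], x$pooled["mean_auc"],
              x$spec$k_folds))
  print(x$per_algorithm, digits = 3)
  invisible(x)
}

# Helper: which subjects were misclassified / correctly classified by ALL
# algorithms (out-of-fold).
classification_masks <- function(eval) {
  ps <- eval$per_subject
  algs <- eval$spec$algorithms
  pred <- as.matrix(ps[paste0("pred_", algs)])
  all_wrong <- rowSums(pred != ps$true) == length(algs)
  all_right <- rowSums(pred == ps$true) == length(algs)
  list(all_wrong = all_wrong, all_right = all_right)
}

#' Select extremes among the subjects misclassified by all algorithms
#'
#' SG candidates: true cases predicted non-case by every algorithm (hearing
#' worse than the risk factors predict). RG candidates: true non-cases
#' predicted case by every algorithm. Within each pool, subjects are ranked
#' by the mean across algorithms of the probability assigned to the (wrong)
#' predicted class and the top `n_per_group` kept.
#'
#' @param x the [cohort()] the model was evaluated on.
#' @param eval a [cross_validated_fit()] result covering `x`.
#' @param n_per_group group quota (the source protocol used 150).
#' @return a `nihl_selection` (method id `"m6"`).
#' @export
select_misclassified_extremes <- function(x, eval, n_per_group = 150) {
  stopifnot(inherits(eval, "nihl_model_eval"), n_per_group >= 1)
  ps <- eval$per_subject
  stopifnot(identical(ps$id, x$id))
  algs <- eval$spec$algorithms
  pc <- as.matrix(ps[paste0("prob_case_", algs)])
  masks <- classification_masks(eval)

  pick <- function(pool, wrong_class_prob) {
    if (!any(pool)) {
      warning("empty misclassified candidate pool", call. = FALSE)
      return(character(0))
    }
    ids <- ps$id[pool]
    sc <- wrong_class_prob[pool]
    ord <- order(-sc, ids)
    ids[head(ord, min(n_per_group, length(ids)))]
  }

  sg_pool <- masks$all_wrong & ps$true == 1   # predicted non-case by all
  rg_pool <- masks$all_wrong & ps$true == 0   # predicted case by all
  mean_wrong_sg <- rowMeans(1 - pc)
  mean_wrong_rg <- rowMeans(pc)

  sg <- pick(sg_pool, mean_wrong_sg)
  rg <- pick(rg_pool, mean_wrong_rg)
  score <- c(setNames(mean_wrong_sg[match(sg, ps$id)], sg),
             setNames(mean_wrong_rg[match(rg, ps$id)], rg))
  selection_result(
    "m6", sg, rg, score,
    metadata = list(n_per_group = n_per_group,
                    pool_sizes = c(sg = sum(sg_pool), rg = sum(rg_pool)),
                    pooled = as.list(eval$pooled),
                    phenotype = list(
                      frequencies = eval$spec$label_rule$frequencies,
                      ear = eval$spec$label_rule$ears)))
}

#' Refine the extreme groups against the correctly classified controls
#'
#' Keeps the top `top_frac` of the SG by phenotype mean HT and drops any
#' kept subject whose HT does not exceed the control mean by more than
#' `sd_multiple` control SDs; symmetrically, keeps the bottom `top_frac` of
#' the RG and requires HT below control mean minus `sd_multiple` SDs. The
#' control group is the set of subjects correctly classified by all
#' algorithms.
#'
#' @param selection a `nihl_selection` (typically from
#'   [select_misclassified_extremes()]).
#' @param x the cohort.
#' @param control_ids ids of the control subjects (must be non-empty).
#' @param frequencies phenotype frequency set; defaults to the selection's.
#' @param top_frac fraction of each group examined (default 0.15).
#' @param sd_multiple SD multiple for the check (default 2).
#' @return a refined `nihl_selection`; metadata records the control mean/sd
#'   and the per-subject check.
#' @export
refine_by_sd <- function(selection, x, control_ids,
                         frequencies = selection$metadata$phenotype$frequencies,
                         top_frac = 0.15, sd_multiple = 2) {
  if (length(control_ids) == 0)
    stop("empty control set")
  stopifnot(top_frac > 0, top_frac <= 1, sd_multiple >= 0)
  ht <- setNames(phenotype_ht(x, frequencies, "bilateral"), x$id)
  ctrl <- ht[control_ids]
  m <- mean(ctrl); s <- sd(ctrl)

  keep_tail <- function(ids, upper) {
    if (length(ids) == 0) return(character(0))
    k <- ceiling(top_frac * length(ids))
    ord <- order(if (upper) -ht[ids] else ht[ids], ids)
    kept <- ids[head(ord, k)]
    if (upper) kept[ht[kept] > m + sd_multiple * s]
    else kept[ht[kept] < m - sd_multiple * s]
  }

  sg <- keep_tail(selection$sg_ids, upper = TRUE)
  rg <- keep_tail(selection$rg_ids, upper = FALSE)
  selection_result(
    selection$method_id, sg, rg,
    score = selection$score[c(sg, rg)],
    metadata = c(selection$metadata,
                 list(refined = TRUE, control_mean = m, control_sd = s,
                      top_frac = top_frac, sd_multiple = sd_multiple,
                      control_n = length(ctrl))))
}

#' Run the full method-6 pipeline
#'
#' Cross-validated fit, misclassification-based selection, and (optionally)
#' SD-based refinement against the correctly classified controls.
#'
#' @param x a study-screened [cohort()].
#' @param spec a [diagnostic_model_spec()].
#' @param n_per_group quota per extreme group.
#' @param refine apply [refine_by_sd()]?
#' @return list with `eval`, `selection`, `refined` (or NULL) and
#'   `control_ids`.
#' @export
run_ml_method <- function(x, spec = diagnostic_model_spec(),
                          n_per_group = 150, refine = TRUE) {
  f <- apply_method_criteria(x, "m6")
  xc <- f$cohort
  eval <- cross_validated_fit(xc, spec)
  sel <- select_misclassified_extremes(xc, eval, n_per_group)
  control_ids <- xc$id[classification_masks(eval)$all_right]
  refined <- if (refine && length(control_ids) > 0)
    refine_by_sd(sel, xc, control_ids) else NULL
  list(eval = eval, selection = sel, refined = refined,
       control_ids = control_ids, filter_report = f$report)
}
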