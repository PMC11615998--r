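make_ml_cohort <- function(n = 400, seed = 1) {
  set.seed(seed)
  tiny_cohort(round(rnorm(n, 30, 10), 1),
              age = round(runif(n, 20, 60), 1),
              leq_8h = round(runif(n, 78, 96), 1),
              exposure_time = round(runif(n, 2, 25), 1),
              sex = ifelse(runif(n) < 0.8, "male", "female"),
              smoking = ifelse(runif(n) < 0.4, "currently", "never"),
              drinking = ifelse(runif(n) < 0.4, "currently", "never"))
}

test_that("a separable label is learned by every algorithm", {
  x <- make_ml_cohort(600, seed = 2)
  # label = indicator(cne > median) and cne is a feature: near-perfect
  thr <- median(phenotype_ht(x, 4))
  df <- as.data.frame(x)
  for (f in NIHL_FREQUENCIES) {  # tie HT deterministically to cne
    df[[paste0("L_", f)]] <- round(df$cne, 1)
    df[[paste0("R_", f)]] <- round(df$cne, 1)
  }
  xs <- cohort(df)
  spec <- diagnostic_model_spec(
    label_rule = label_rule(4, "bilateral", median(df$cne)),
    k_folds = 5, seed = 3)
  ev <- cross_validated_fit(xs, spec)
  expect_true(all(ev$per_algorithm$mean_accuracy >= 0.95))
  expect_true(all(ev$per_algorithm$mean_auc >= 0.95))
})

test_that("permuted labels give null AUC around 0.5", {
  x <- make_ml_cohort(2000, seed = 4)
  # thresholds independent of all covariates by construction
  set.seed(9)
  df <- as.data.frame(x)
  for (f in NIHL_FREQUENCIES) {
    v <- round(rnorm(nrow(df), 30, 15), 1)
    df[[paste0("L_", f)]] <- v
    df[[paste0("R_", f)]] <- v
  }
  ev <- cross_validated_fit(
    cohort(df),
    diagnostic_model_spec(label_rule = label_rule(4, "bilateral", 30),
                          k_folds = 10, seed = 5))
  expect_true(all(abs(ev$per_algorithm$mean_auc - 0.5) < 0.05))
})

test_that("every subject gets exactly one out-of-fold prediction per algorithm", {
  x <- tiny_cohort(c(10, 40, 12, 38), age = c(30, 50, 32, 52))
  ev <- cross_validated_fit(
    x, diagnostic_model_spec(label_rule = label_rule(4, "bilateral", 25),
                             k_folds = 2, seed = 1))
  ps <- ev$per_subject
  expect_setequal(ps$id, x$id)
  expect_equal(anyDuplicated(ps$id), 0)
  for (alg in NIHL_ALGORITHMS)
    expect_true(all(is.finite(ps[[paste0("prob_case_", alg)]])))
})

test_that("single-class labels and spec violations error", {
  x <- make_ml_cohort(60)
  expect_error(cross_validated_fit(
    x, diagnostic_model_spec(label_rule = label_rule(4, "bilateral", 1000))),
    "single class")
  expect_error(diagnostic_model_spec(k_folds = 1))
  expect_error(diagnostic_model_spec(algorithms = character(0)))
  expect_error(diagnostic_model_spec(features = "shoe_size"))
})

test_that("misclassified-extreme selection applies the published rule", {
  # one algorithm, 3 subjects: true (1,1,0), predicted (0,1,1),
  # probabilities of the predicted class (0.9, 0.8, 0.7)
  x <- tiny_cohort(c(50, 50, 10))
  eval <- structure(list(
    per_subject = data.frame(
      id = x$id, true = c(1L, 1L, 0L),
      pred_svm = c(0L, 1L, 1L),
      prob_case_svm = c(0.1, 0.8, 0.7)),
    spec = list(algorithms = "svm",
                label_rule = label_rule(c(4, 12.5)))),
    class = "nihl_model_eval")
  sel <- select_misclassified_extremes(x, eval, n_per_group = 150)
  expect_equal(sel$sg_ids, "w01")
  expect_equal(sel$rg_ids, "w03")
  expect_equal(unname(sel$score["w01"]), 0.9)
  expect_equal(unname(sel$score["w03"]), 0.7)
  # n_per_group clamps to the pool
  sel1 <- select_misclassified_extremes(x, eval, n_per_group = 1)
  expect_length(sel1$sg_ids, 1)
  # empty pool warns, does not error
  eval$per_subject$pred_svm <- eval$per_subject$true
  expect_warning(  # both pools are empty -> one warning per group
    expect_warning(sel0 <- select_misclassified_extremes(x, eval, 5),
                   "empty"),
    "empty")
  expect_length(sel0$sg_ids, 0)
})

test_that("SD refinement keeps only subjects beyond the control band", {
  # control mean 10, sd 2: an SG candidate at 58.8 dB is retained
  ctrl_ht <- c(8, 10, 12)           # mean 10, sd 2
  x <- tiny_cohort(c(ctrl_ht, 58.8, 13.9, 5.5))
  sel <- structure(
    list(method_id = "m6", sg_ids = c("w04", "w05"), rg_ids = "w06",
         score = c(w04 = .9, w05 = .8, w06 = .7),
         metadata = list(phenotype = list(frequencies = c(4, 12.5),
                                          ear = "bilateral"))),
    class = "nihl_selection")
  ref <- refine_by_sd(sel, x, control_ids = c("w01", "w02", "w03"),
                      top_frac = 1, sd_multiple = 2)
  expect_equal(ref$sg_ids, "w04")   # 58.8 > 14; 13.9 is not
  expect_equal(ref$rg_ids, "w06")   # 6 < 10 - 4
  # sd_multiple 0 reduces to a mean comparison
  ref0 <- refine_by_sd(sel, x, c("w01", "w02", "w03"), top_frac = 1,
                       sd_multiple = 0)
  expect_setequal(ref0$sg_ids, c("w04", "w05"))
  # refinement is contractive
  expect_true(all(ref$sg_ids %in% sel$sg_ids))
  expect_true(all(ref$rg_ids %in% sel$rg_ids))
  expect_error(refine_by_sd(sel, x, character(0)), "empty control")
})

test_that("method-6 pools are disjoint and the pipeline is reproducible", {
  x <- make_ml_cohort(500, seed = 6)
  spec <- diagnostic_model_spec(label_rule = label_rule(4, "bilateral", 30),
                                k_folds = 5, seed = 11)
  r1 <- run_ml_method(x, spec, n_per_group = 20, refine = TRUE)
  r2 <- run_ml_method(x, spec, n_per_group = 20, refine = TRUE)
  expect_identical(r1$selection$sg_ids, r2$selection$sg_ids)
  expect_identical(r1$eval$per_algorithm, r2$eval$per_algorithm)
  expect_length(intersect(r1$selection$sg_ids, r1$selection$rg_ids), 0)
  # SG candidates are true cases, RG candidates true non-cases
  ps <- r1$eval$per_subject
  expect_true(all(ps$true[match(r1$selection$sg_ids, ps$id)] == 1))
  expect_true(all(ps$true[match(r1$selection$rg_ids, ps$id)] == 0))
})
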