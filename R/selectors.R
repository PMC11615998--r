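# The five non-ML extreme-group selection procedures.
#
# Shared conventions: selection counts use floor(fraction * n); ranking is
# ascending in the selection score with the worker id as the final sort key,
# so results are invariant to the input row order; the susceptible group
# (SG) is the high-score tail (worse hearing), the resistant group (RG) the
# low-score tail.

selection_result <- function(method_id, sg_ids, rg_ids, score, metadata) {
  if (length(intersect(sg_ids, rg_ids)) > 0)
    stop("SG and RG overlap")
  structure(list(method_id = method_id,
                 sg_ids = sg_ids, rg_ids = rg_ids,
                 score = score, metadata = metadata),
            class = "nihl_selection")
}

#' @export
print.nihl_selection <- function(x, ...) {
  cat(sprintf("<selection %s> SG n=%d, RG n=%d\n",
              x$method_id, length(x$sg_ids), length(x$rg_ids)))
  invisible(x)
}

# Ascending rank with id tie-break; returns the ids of the k lowest / k
# highest scores.
tail_ids <- function(ids, score, k) {
  ord <- order(score, ids)
  list(low = ids[head(ord, k)], high = ids[utils::tail(ord, k)])
}

#' Stratum grid for the stratified percentile selectors
#'
#' Bins use left-closed intervals (`[a, b)`), so a worker exactly on an
#' inner edge falls in the upper bin.
#'
#' @param axis1_var,axis2_var column names (e.g. `"exposure_time"`,
#'   `"leq_8h"`, `"age"`).
#' @param axis1_breaks,axis2_breaks full break vectors including `-Inf` and
#'   `Inf`.
#' @return a `nihl_stratum_spec`.
#' @export
stratum_spec <- function(axis1_var, axis1_breaks, axis2_var, axis2_breaks) {
  stopifnot(!is.unsorted(axis1_breaks), !is.unsorted(axis2_breaks))
  structure(list(axis1 = list(var = axis1_var, breaks = axis1_breaks),
                 axis2 = list(var = axis2_var, breaks = axis2_breaks)),
            class = "nihl_stratum_spec")
}

#' Method 1/2 style: percentile extremes within covariate strata
#'
#' Workers are cross-classified on two covariate axes; within each stratum
#' the `fraction` with the highest mean hearing threshold (HT) over the
#' phenotype frequencies goes to the SG and the `fraction` with the lowest
#' to the RG. Strata with fewer than `ceiling(1/fraction)` workers cannot
#' contribute one worker per tail and are skipped with a warning.
#'
#' @param x a filtered [cohort()].
#' @param strata a [stratum_spec()].
#' @param frequencies phenotype frequency set (kHz).
#' @param ear `"left"`, `"right"` or `"bilateral"`.
#' @param fraction tail fraction in (0, 0.5].
#' @param method_id label recorded in the result.
#' @return a `nihl_selection`.
#' @export
select_stratified_extremes <- function(x, strata, frequencies,
                                       ear = "left", fraction = 0.2,
                                       method_id = "stratified") {
  stopifnot(inherits(strata, "nihl_stratum_spec"),
            fraction > 0, fraction <= 0.5)
  score_all <- phenotype_ht(x, frequencies, ear)
  b1 <- cut(x[[strata$axis1$var]], strata$axis1$breaks, right = FALSE)
  b2 <- cut(x[[strata$axis2$var]], strata$axis2$breaks, right = FALSE)
  key <- interaction(b1, b2, drop = TRUE)

  sg <- rg <- character(0)
  strata_used <- list()
  for (lev in levels(key)) {
    in_s <- which(key == lev)
    k <- floor(fraction * length(in_s))
    if (length(in_s) < ceiling(1 / fraction) || k < 1) {
      warning("stratum ", lev, " has ", length(in_s),
              " workers; skipped", call. = FALSE)
      next
    }
    t <- tail_ids(x$id[in_s], score_all[in_s], k)
    sg <- c(sg, t$high)
    rg <- c(rg, t$low)
    strata_used[[lev]] <- length(in_s)
  }
  sel <- c(sg, rg)
  selection_result(method_id, sg, rg,
                   score = setNames(score_all[match(sel, x$id)], sel),
                   metadata = list(strata = strata_used,
                                   fraction = fraction,
                                   phenotype = list(
                                     frequencies = frequencies, ear = ear)))
}

#' Method 3: bidimensional standardized-threshold extremes
#'
#' Thresholds at two frequencies are z-scored over the filtered cohort and
#' plotted on a Cartesian plane; the extremity score is the projection onto
#' the main diagonal, `(z_x + z_y) / 2` (the unique symmetric linear
#' choice). The top `fraction` goes to the SG, the bottom to the RG.
#'
#' @inheritParams select_stratified_extremes
#' @param fx,fy the two frequencies (kHz).
#' @return a `nihl_selection`.
#' @export
select_bidimensional_extremes <- function(x, fx = 4, fy = 6, ear = "left",
                                          fraction = 0.1,
                                          method_id = "bidimensional") {
  stopifnot(fraction > 0, fraction <= 0.5)
  hx <- phenotype_ht(x, fx, ear)
  hy <- phenotype_ht(x, fy, ear)
  if (sd(hx) == 0 || sd(hy) == 0)
    stop("zero variance on a threshold axis")
  score_all <- (scale(hx)[, 1] + scale(hy)[, 1]) / 2
  k <- floor(fraction * nrow(x))
  t <- tail_ids(x$id, score_all, k)
  sel <- c(t$high, t$low)
  selection_result(method_id, t$high, t$low,
                   score = setNames(score_all[match(sel, x$id)], sel),
                   metadata = list(fraction = fraction,
                                   phenotype = list(
                                     frequencies = c(fx, fy), ear = ear)))
}

#' Methods 4/5: dose-residual extremes
#'
#' Fits least squares of the bilateral mean HT over the phenotype
#' frequencies on CNE (linear or quadratic) and ranks workers by the
#' residual `r = measured - predicted`. Positive extremes (hearing worse
#' than the dose predicts) form the SG, negative extremes the RG.
#'
#' @inheritParams select_stratified_extremes
#' @param model `"linear"` or `"quadratic"` in CNE.
#' @return a `nihl_selection`; metadata records coefficients and R^2.
#' @export
select_residual_extremes <- function(x, frequencies = c(3, 4, 6),
                                     model = c("linear", "quadratic"),
                                     fraction = 0.1,
                                     method_id = "residual") {
  model <- match.arg(model)
  stopifnot(nrow(x) >= 10, fraction > 0, fraction <= 0.5)
  y <- phenotype_ht(x, frequencies, "bilateral")
  if (var(x$cne) == 0)
    stop("degenerate design: CNE has zero variance")
  fit <- if (model == "linear") lm(y ~ cne, data = as.data.frame(x))
         else lm(y ~ cne + I(cne^2), data = as.data.frame(x))
  if (anyNA(coef(fit)))
    stop("degenerate (collinear) regression design")
  r <- y - predict(fit)
  k <- floor(fraction * nrow(x))
  t <- tail_ids(x$id, r, k)
  sel <- c(t$high, t$low)
  selection_result(method_id, t$high, t$low,
                   score = setNames(r[match(sel, x$id)], sel),
                   metadata = list(model = model,
                                   coefficients = coef(fit),
                                   r_squared = summary(fit)$r.squared,
                                   fraction = fraction,
                                   phenotype = list(
                                     frequencies = frequencies,
                                     ear = "bilateral")))
}

#' Run one of the five classical methods with its published settings
#'
#' Applies the method's inclusion/exclusion criteria
#' ([apply_method_criteria()]) and then its selector:
#' * m1: exposure-years strata `{<15, 15-25, >=25}` x noise strata
#'   `{<85, 85-91.5, >=91.5}` dBA, 20% tails, left ear at 4 and 6 kHz.
#' * m2: age strata `{<35, 35-50, >=50}` x the same noise strata, 10%
#'   tails, left ear at 3 kHz.
#' * m3: bidimensional z-cut at 4 and 6 kHz (left ear), 10% tails.
#' * m4: linear residual of bilateral 3, 4, 6 kHz HT on CNE, 10% tails.
#' * m5: quadratic residual of the same phenotype, 20% tails.
#'
#' @param x a study-screened [cohort()].
#' @param method_id `"m1" ... "m5"`.
#' @return `list(selection=, filter_report=)`.
#' @export
run_classical_method <- function(x, method_id) {
  stopifnot(method_id %in% paste0("m", 1:5))
  f <- apply_method_criteria(x, method_id)
  xc <- f$cohort
  noise_breaks <- c(-Inf, 85, 91.5, Inf)
  sel <- switch(
    method_id,
    m1 = select_stratified_extremes(
      xc, stratum_spec("exposure_time", c(-Inf, 15, 25, Inf),
                       "leq_8h", noise_breaks),
      frequencies = c(4, 6), ear = "left", fraction = 0.20,
      method_id = "m1"),
    m2 = select_stratified_extremes(
      xc, stratum_spec("age", c(-Inf, 35, 50, Inf),
                       "leq_8h", noise_breaks),
      frequencies = 3, ear = "left", fraction = 0.10, method_id = "m2"),
    m3 = select_bidimensional_extremes(xc, 4, 6, ear = "left",
                                       fraction = 0.10, method_id = "m3"),
    m4 = select_residual_extremes(xc, c(3, 4, 6), "linear",
                                  fraction = 0.10, method_id = "m4"),
    m5 = select_residual_extremes(xc, c(3, 4, 6), "quadratic",
                                  fraction = 0.20, method_id = "m5"))
  list(selection = sel, filter_report = f$report)
}
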