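# Face-validity assessment: a selection method is credible when its
# susceptible group is younger, shorter-exposed and lower-dosed yet
# worse-hearing than its resistant group. Concordance with those expected
# directions is counted over significant two-sided tests.

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p by enumeration over all labelings when both samples have at most
#' 8 observations and there are no ties; otherwise the normal approximation
#' with midrank ties and tie-corrected variance (no continuity correction).
#'
#' @param x,y numeric samples (non-empty).
#' @return `list(statistic = U of x, p_value)`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  no_ties <- !anyDuplicated(pooled)

  if (n1 <= 8 && n2 <= 8 && no_ties) {
    # exact: U is symmetric about n1*n2/2 under H0
    combos <- combn(n1 + n2, n1)
    us <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    lo <- min(U, n1 * n2 - U)
    p <- min(1, 2 * mean(us <= lo))
    return(list(statistic = U, p_value = p))
  }

  N <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0)
    return(list(statistic = U, p_value = 1))
  z <- (U - n1 * n2 / 2) / sqrt(v)
  list(statistic = U, p_value = min(1, 2 * pnorm(-abs(z))))
}

#' Pearson chi-square test for a 2x2 table (no continuity correction)
#'
#' Statistic `n (ad - bc)^2 / (r1 r2 c1 c2)` referred to chi-square with
#' 1 df.
#'
#' @param a,b,c,d cell counts (row-wise).
#' @return `list(statistic, p_value)`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0))
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    stop("zero margin in 2x2 table")
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

compare_continuous <- function(sg, rg, variable, expected, alpha) {
  if (length(sg) < 2 || length(rg) < 2) {
    return(list(variable = variable, expected_direction = expected,
                indeterminate = TRUE, concordant = NA,
                significant = NA, p_value = NA_real_))
  }
  t <- rank_sum_test(sg, rg)
  q <- function(v) quantile(v, c(0.5, 0.25, 0.75), names = FALSE)
  sig <- t$p_value < alpha
  dir <- if (median(sg) < median(rg)) "sg_lower"
         else if (median(sg) > median(rg)) "sg_higher" else "equal"
  list(variable = variable,
       sg_summary = q(sg), rg_summary = q(rg),
       statistic = t$statistic, p_value = t$p_value,
       expected_direction = expected,
       significant = sig,
       observed_direction = dir,
       concordant = if (expected == "none") NA else sig && dir == expected,
       indeterminate = FALSE)
}

#' Face-validity assessment of one selection
#'
#' Compares SG vs RG on age, exposure time and CNE (all expected lower in
#' the SG), the phenotype mean HT (expected higher in the SG), and the sex
#' proportion (no expected direction; Pearson chi-square). A comparison is
#' concordant when it is significant at `alpha` AND in the expected
#' direction; discordant-significant comparisons (the classic failure of
#' raw-threshold selectors: an older SG) are counted separately.
#'
#' @param x the filtered [cohort()] the selection was made from.
#' @param selection a `nihl_selection`.
#' @param alpha significance level (default 0.05, two-sided).
#' @return a `nihl_face_validity`: `method_id`, `n_expected`,
#'   `n_concordant`, `n_discordant_significant`, `detail`.
#' @export
assess_method <- function(x, selection, alpha = 0.05) {
  sg <- selection$sg_ids; rg <- selection$rg_ids
  stopifnot(length(sg) > 0, length(rg) > 0)
  isg <- match(sg, x$id); irg <- match(rg, x$id)
  if (anyNA(isg) || anyNA(irg))
    stop("selection contains ids not in the cohort")

  ph <- selection$metadata$phenotype
  pheno <- phenotype_ht(x, ph$frequencies, ph$ear)

  detail <- list(
    compare_continuous(x$age[isg], x$age[irg], "age", "sg_lower", alpha),
    compare_continuous(x$exposure_time[isg], x$exposure_time[irg],
                       "exposure_time", "sg_lower", alpha),
    compare_continuous(x$cne[isg], x$cne[irg], "cne", "sg_lower", alpha),
    compare_continuous(pheno[isg], pheno[irg], "phenotype_ht", "sg_higher",
                       alpha))

  sex_tab <- c(a = sum(x$sex[isg] == "male"),
               b = sum(x$sex[isg] == "female"),
               c = sum(x$sex[irg] == "male"),
               d = sum(x$sex[irg] == "female"))
  sex_cmp <- tryCatch({
    t <- chi_square_2x2(sex_tab["a"], sex_tab["b"], sex_tab["c"],
                        sex_tab["d"])
    list(variable = "sex_male_prop",
         sg_summary = unname(sex_tab["a"] / length(sg)),
         rg_summary = unname(sex_tab["c"] / length(rg)),
         statistic = unname(t$statistic), p_value = unname(t$p_value),
         expected_direction = "none", significant = t$p_value < alpha,
         concordant = NA, indeterminate = FALSE)
  }, error = function(e) list(variable = "sex_male_prop",
                              expected_direction = "none",
                              concordant = NA, significant = NA,
                              p_value = NA_real_, indeterminate = TRUE))
  detail <- c(detail, list(sex_cmp))

  directional <- Filter(function(d) !identical(d$expected_direction, "none"),
                        detail)
  conc <- vapply(directional, function(d) isTRUE(d$concordant), logical(1))
  disc <- vapply(directional, function(d)
    isTRUE(d$significant) && isFALSE(d$concordant), logical(1))

  structure(list(method_id = selection$method_id,
                 n_expected = length(directional),
                 n_concordant = sum(conc),
                 n_discordant_significant = sum(disc),
                 detail = detail),
            class = "nihl_face_validity")
}

#' @export
print.nihl_face_validity <- function(x, ...) {
  cat(sprintf("<face validity %s> %d/%d concordant (%d discordant)\n",
              x$method_id, x$n_concordant, x$n_expected,
              x$n_discordant_significant))
  invisible(x)
}

#' Rank methods by face validity
#'
#' Concordance count descending; ties broken by fewer
#' discordant-significant comparisons, then by method id.
#'
#' @param scores list of [assess_method()] results.
#' @return the list, reordered best-first.
#' @export
rank_methods <- function(scores) {
  stopifnot(length(scores) > 0)
  nc <- vapply(scores, `[[`, numeric(1), "n_concordant")
  nd <- vapply(scores, `[[`, numeric(1), "n_discordant_significant")
  ids <- vapply(scores, `[[`, character(1), "method_id")
  scores[order(-nc, nd, ids)]
}
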