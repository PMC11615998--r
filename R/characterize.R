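# Characterization of the final susceptible / resistant / control groups:
# median-IQR summaries mirroring the published group tables and
# zero-intercept hearing-loss growth slopes versus exposure time.

#' Least-squares slope through the origin
#'
#' Fits `HT = slope * exposure_time` by least squares with the intercept
#' forced to 0: `slope = sum(t * h) / sum(t^2)`.
#'
#' @param exposure_time years (at least one positive value).
#' @param ht hearing thresholds, dB.
#' @return `list(slope, n)` with slope in dB per year.
#' @export
fit_zero_intercept_slope <- function(exposure_time, ht) {
  stopifnot(length(exposure_time) == length(ht), length(ht) >= 1)
  if (all(exposure_time == 0))
    stop("all exposure times are zero")
  list(slope = sum(exposure_time * ht) / sum(exposure_time^2),
       n = length(ht))
}

#' Pooled growth slopes for each group and frequency set
#'
#' Per group, all (exposure time, HT) points are pooled and a single
#' zero-intercept line fitted (the published scatter fits are pooled, not
#' per subject).
#'
#' @param x a [cohort()].
#' @param groups named list of id vectors (e.g. `list(sg=, control=, rg=)`).
#' @param freq_sets named list of frequency vectors.
#' @param ear ear selection for [phenotype_ht()].
#' @return data.frame: group, freq_set, slope (dB/year), n.
#' @export
group_slopes <- function(x, groups,
                         freq_sets = list("4" = 4, "12.5" = 12.5,
                                          "0.5-2" = c(0.5, 1, 2),
                                          "4+12.5" = c(4, 12.5)),
                         ear = "bilateral") {
  rows <- list()
  for (g in names(groups)) {
    idx <- match(groups[[g]], x$id)
    stopifnot(!anyNA(idx))
    for (fs in names(freq_sets)) {
      ht <- phenotype_ht(x, freq_sets[[fs]], ear)[idx]
      fit <- fit_zero_intercept_slope(x$exposure_time[idx], ht)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, freq_set = fs, slope = fit$slope, n = fit$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median/IQR group summary
#'
#' Medians and linear-interpolation quartiles (R quantile type 7) for age,
#' exposure time, CNE and the mean HT over each configured frequency set;
#' sex counts with proportions.
#'
#' @param x a [cohort()].
#' @param ids worker ids forming the group.
#' @param freq_sets named list of frequency sets summarized as PTAs.
#' @param ear ear selection.
#' @return a `nihl_group_summary` list.
#' @export
summarize_group <- function(x, ids,
                            freq_sets = list("0.5-2" = c(0.5, 1, 2),
                                             "3" = 3, "4" = 4, "6" = 6,
                                             "10" = 10, "12.5" = 12.5,
                                             "4+12.5" = c(4, 12.5)),
                            ear = "bilateral") {
  stopifnot(length(ids) > 0)
  idx <- match(ids, x$id)
  if (anyNA(idx))
    stop("unknown worker id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  miqr <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    c(median = q[2], q1 = q[1], q3 = q[3])
  }
  vars <- list(age = x$age[idx],
               exposure_time = x$exposure_time[idx],
               cne = x$cne[idx])
  for (fs in names(freq_sets))
    vars[[paste0("pta_", fs)]] <- phenotype_ht(x, freq_sets[[fs]], ear)[idx]

  structure(list(
    n = length(idx),
    sex_counts = c(male = sum(x$sex[idx] == "male"),
                   female = sum(x$sex[idx] == "female")),
    medians_iqr = lapply(vars, miqr)),
    class = "nihl_group_summary")
}

#' @export
print.nihl_group_summary <- function(x, ...) {
  cat(sprintf("<group summary> n=%d (male %d, female %d)\n", x$n,
              x$sex_counts["male"], x$sex_counts["female"]))
  for (v in names(x$medians_iqr)) {
    m <- x$medians_iqr[[v]]
    cat(sprintf("  %-14s %.1f (%.1f-%.1f)\n", v, m["median"], m["q1"],
                m["q3"]))
  }
  invisible(x)
}

#' Combined pure-tone average for single workers
#'
#' Unweighted mean of thresholds over a frequency set for the selected
#' ear(s); with `ear = "bilateral"` this is the mean over all ear-frequency
#' values.
#'
#' @param x a [cohort()].
#' @param id one worker id.
#' @param frequencies frequency set (kHz).
#' @param ear `"left"`, `"right"` or `"bilateral"`.
#' @return dB HL scalar.
#' @export
combined_pta <- function(x, id, frequencies, ear = "bilateral") {
  idx <- match(id, x$id)
  if (is.na(idx)) stop("unknown worker id: ", id)
  unname(phenotype_ht(subset_cohort(x, idx), frequencies, ear))
}
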