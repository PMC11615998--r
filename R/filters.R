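# Study-level and per-method inclusion/exclusion rules.
#
# Rules are an ordered list; each worker is removed under the FIRST rule it
# matches, so the report's per-rule counts partition the removals.
# Unverifiable medical-history criteria (meningitis, ototoxic drugs, head
# injury, acoustic trauma, ...) are optional boolean columns defaulting to
# absent, which keeps the rule engine complete without inventing data.

filter_report <- function(input_count, output_count, removed_by_rule,
                          unscreenable = 0L) {
  stopifnot(input_count == output_count + sum(unlist(removed_by_rule)))
  structure(list(input_count = as.integer(input_count),
                 output_count = as.integer(output_count),
                 removed_by_rule = removed_by_rule,
                 unscreenable = as.integer(unscreenable)),
            class = "nihl_filter_report")
}

#' @export
print.nihl_filter_report <- function(x, ...) {
  cat(sprintf("<filter report> %d -> %d workers\n",
              x$input_count, x$output_count))
  for (r in names(x$removed_by_rule))
    cat(sprintf("  removed by %-28s %d\n", paste0(r, ":"),
                x$removed_by_rule[[r]]))
  if (x$unscreenable > 0)
    cat(sprintf("  retained but unscreenable:     %d\n", x$unscreenable))
  invisible(x)
}

bool_col <- function(x, name) {
  if (name %in% names(x)) as.logical(x[[name]]) else rep(FALSE, nrow(x))
}

# Apply an ordered named list of logical removal masks; first match wins.
apply_rules <- function(x, rules, unscreenable = 0L) {
  removed <- rep(FALSE, nrow(x))
  counts <- list()
  for (rn in names(rules)) {
    hit <- rules[[rn]] & !removed
    counts[[rn]] <- sum(hit)
    removed <- removed | hit
  }
  out <- subset_cohort(x, !removed)
  list(cohort = out,
       report = filter_report(nrow(x), nrow(out), counts, unscreenable))
}

# Largest absolute left-right threshold gap over a frequency set.
interaural_gap <- function(x, frequencies) {
  gaps <- abs(ht_matrix(x, "left", frequencies) -
                ht_matrix(x, "right", frequencies))
  apply(gaps, 1, max)
}

#' Study-level exclusions
#'
#' Removes workers with pre-existing hearing loss (any pre-employment
#' threshold >= 25 dB HL at 0.5-6 kHz) and workers with less than one year
#' of industrial noise exposure. Workers lacking a pre-employment audiogram
#' are retained and counted as `unscreenable` in the report (real CSVs may
#' omit the pre-employment columns).
#'
#' @param x a [cohort()].
#' @return `list(cohort=, report=)`.
#' @export
apply_study_exclusions <- function(x) {
  stopifnot(inherits(x, "nihl_cohort"), nrow(x) > 0)
  pre_cols <- intersect(freq_cols("PRE", NIHL_CONVENTIONAL), names(x))
  if (length(pre_cols) > 0) {
    pre <- as.matrix(as.data.frame(x)[, pre_cols, drop = FALSE])
    screenable <- rowSums(is.na(pre)) == 0
    preexisting <- screenable & apply(pre >= 25, 1, any)
  } else {
    screenable <- rep(FALSE, nrow(x))
    preexisting <- rep(FALSE, nrow(x))
  }
  rules <- list(
    "preexisting_loss_ge25dB" = preexisting,
    "exposure_lt_1yr" = x$exposure_time < 1)
  apply_rules(x, rules, unscreenable = sum(!screenable))
}

method_ids <- paste0("m", 1:6)

#' Per-method inclusion/exclusion criteria
#'
#' Applies the published criteria of one of the six selection methods to an
#' already study-screened cohort:
#' * `m1`: drops medical-history positives (meningitis, aminoglycoside
#'   treatment, acoustic trauma), inter-aural gap >= 40 dB at 0.5-6 kHz,
#'   exposure < 5 years, females, and careers longer than
#'   `0.666 * age - 20` years.
#' * `m2`: drops medical-history positives (head injury, otologic disease,
#'   ototoxic drugs) and hearing-protector non-users.
#' * `m3`: drops exposure < 1 year, middle-ear disease, air-bone gap, and
#'   inter-aural gap >= 40 dB at 4 and 6 kHz.
#' * `m4`: keeps CNE > 80 dBA-years.
#' * `m5`: keeps exposure > 1 year, drops medical-history positives.
#' * `m6`: study-level criteria only (identity here).
#'
#' The gap criteria are printed as "< 40 dB" in the source table, which read
#' literally would exclude nearly everyone; they are implemented reversed
#' (exclude asymmetric loss >= 40 dB).
#'
#' @param x a [cohort()].
#' @param method_id one of `"m1" ... "m6"`.
#' @return `list(cohort=, report=)`.
#' @export
apply_method_criteria <- function(x, method_id) {
  stopifnot(inherits(x, "nihl_cohort"))
  if (!method_id %in% method_ids)
    stop("unknown method_id: ", method_id)
  rules <- switch(
    method_id,
    m1 = list(
      "history_meningitis" = bool_col(x, "meningitis"),
      "history_aminoglycoside" = bool_col(x, "aminoglycoside"),
      "history_acoustic_trauma" = bool_col(x, "acoustic_trauma"),
      "interaural_gap_ge40dB" =
        interaural_gap(x, NIHL_CONVENTIONAL) >= 40,
      "exposure_lt_5yr" = x$exposure_time < 5,
      "female" = x$sex == "female",
      "duration_gt_0.666age_minus_20" =
        x$exposure_time > (0.666 * x$age - 20)),
    m2 = list(
      "history_head_injury_or_otologic" =
        bool_col(x, "head_injury") | bool_col(x, "otologic_disease"),
      "history_ototoxic_drugs" = bool_col(x, "ototoxic_drugs"),
      "no_hearing_protector" = bool_col(x, "hearing_protector_nonuse")),
    m3 = list(
      "exposure_lt_1yr" = x$exposure_time < 1,
      "history_middle_ear_disease" = bool_col(x, "middle_ear_disease"),
      "air_bone_gap" = bool_col(x, "air_bone_gap"),
      "interaural_gap_ge40dB" = interaural_gap(x, c(4, 6)) >= 40),
    m4 = list("cne_le_80dBAy" = x$cne <= 80),
    m5 = list(
      "exposure_le_1yr" = x$exposure_time <= 1,
      "history_hearing_impairment" =
        bool_col(x, "ototoxic_drugs") | bool_col(x, "head_injury") |
        bool_col(x, "otologic_disease")),
    m6 = list())
  apply_rules(x, rules)
}
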