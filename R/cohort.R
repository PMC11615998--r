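#' @useDynLib nihlscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median model.matrix optim pchisq pnorm quantile rbinom
#'   rlnorm rnorm runif sd setNames cor lm coef predict var glm binomial
#'   plogis qnorm
#' @importFrom utils read.csv write.csv combn head modifyList
NULL

#' Audiometric frequency grid used throughout the package (kHz)
#'
#' Conventional frequencies 0.5-6 kHz plus the extended high frequencies
#' (EHF) 10 and 12.5 kHz.
#' @export
NIHL_FREQUENCIES <- c(0.5, 1, 2, 3, 4, 6, 10, 12.5)

#' Conventional screening band (kHz) used by the pre-employment exclusion
#' @export
NIHL_CONVENTIONAL <- c(0.5, 1, 2, 3, 4, 6)

freq_cols <- function(prefix, freqs) paste0(prefix, "_", freqs)

#' Construct a worker cohort
#'
#' A cohort is a `data.frame` (class `nihl_cohort`) with one row per worker
#' and per-ear hearing thresholds (dB HL) in columns `L_<f>` / `R_<f>` for
#' each frequency `f` on the grid. Optional columns: `PRE_<f>` for the
#' pre-employment audiogram at the conventional frequencies, `latent_s` for
#' the latent susceptibility factor of synthetic cohorts, and boolean
#' history columns used by per-method exclusion rules.
#'
#' @param df data.frame with at least `id`, `sex`, `age`, `exposure_time`,
#'   `leq_8h`, `cne`, `smoking`, `drinking` and the `L_*`/`R_*` threshold
#'   columns.
#' @param frequencies ordered numeric frequency grid in kHz.
#' @param provenance free-form list (seed, parameter hash, ...).
#' @return A `nihl_cohort` object.
#' @export
cohort <- function(df, frequencies = NIHL_FREQUENCIES, provenance = list()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("id", "sex", "age", "exposure_time", "leq_8h", "cne",
           "smoking", "drinking",
           freq_cols("L", frequencies), freq_cols("R", frequencies))
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("worker ids must be unique")
  df$id <- as.character(df$id)
  rownames(df) <- NULL
  structure(df,
            frequencies = as.numeric(frequencies),
            provenance = provenance,
            class = c("nihl_cohort", "data.frame"))
}

#' @export
print.nihl_cohort <- function(x, ...) {
  cat(sprintf("<nihl_cohort> %d workers, frequencies (kHz): %s\n",
              nrow(x), paste(attr(x, "frequencies"), collapse = ", ")))
  prov <- attr(x, "provenance")
  if (length(prov) > 0)
    cat("  provenance:", paste(names(prov), unlist(lapply(prov, format)),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Frequencies of a cohort
#' @param x a `nihl_cohort`.
#' @return numeric vector of kHz values.
#' @export
cohort_frequencies <- function(x) attr(x, "frequencies")

# Subset rows of a cohort, preserving attributes.
subset_cohort <- function(x, keep) {
  out <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            frequencies = attr(x, "frequencies"),
            provenance = attr(x, "provenance"),
            class = class(x))
}

#' Per-ear threshold matrix
#'
#' @param x a `nihl_cohort`.
#' @param ear `"left"`, `"right"` or `"bilateral"` (elementwise mean of the
#'   two ears).
#' @param frequencies subset of the grid (default: whole grid).
#' @return numeric matrix, workers x frequencies (columns named by kHz).
#' @export
ht_matrix <- function(x, ear = c("left", "right", "bilateral"),
                      frequencies = cohort_frequencies(x)) {
  ear <- match.arg(ear)
  bad <- setdiff(frequencies, cohort_frequencies(x))
  if (length(bad) > 0)
    stop("frequencies not on the cohort grid: ", paste(bad, collapse = ", "))
  get <- function(prefix) {
    m <- as.matrix(as.data.frame(x)[, freq_cols(prefix, frequencies),
                                    drop = FALSE])
    colnames(m) <- as.character(frequencies)
    m
  }
  switch(ear,
         left = get("L"),
         right = get("R"),
         bilateral = (get("L") + get("R")) / 2)
}

#' Mean hearing threshold over a frequency set (per worker)
#'
#' @inheritParams ht_matrix
#' @return numeric vector (one value per worker), dB HL.
#' @export
phenotype_ht <- function(x, frequencies, ear = "bilateral") {
  rowMeans(ht_matrix(x, ear = ear, frequencies = frequencies))
}

#' Read / write the cohort CSV interchange format
#'
#' One row per worker; header mandatory; UTF-8; decimal point. Threshold
#' columns are `L_0.5 ... L_12.5`, `R_0.5 ... R_12.5`, optionally
#' `PRE_0.5 ... PRE_6` and `latent_s`.
#'
#' @param path file path.
#' @param frequencies frequency grid expected in the file.
#' @return `read_cohort_csv` returns a `nihl_cohort`;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path, frequencies = NIHL_FREQUENCIES) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 fileEncoding = "UTF-8")
  cohort(df, frequencies = frequencies,
         provenance = list(source = basename(path)))
}

#' @rdname read_cohort_csv
#' @param x a `nihl_cohort`.
#' @export
write_cohort_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
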