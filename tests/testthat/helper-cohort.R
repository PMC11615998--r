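# Fixtures are built in code. tiny_cohort() gives exact control over the
# per-worker thresholds (one value replicated over all frequencies and both
# ears unless overridden); shared_cohort() lazily builds and caches the
# default synthetic cohorts reused across test files.

tiny_cohort <- function(ht, ids = sprintf("w%02d", seq_along(ht)),
                        age = 40, exposure_time = 10, leq_8h = 85,
                        sex = "male", smoking = "never", drinking = "never",
                        ht_right = ht) {
  n <- length(ht)
  df <- data.frame(id = ids, sex = rep_len(sex, n),
                   age = rep_len(age, n),
                   exposure_time = rep_len(exposure_time, n),
                   leq_8h = rep_len(leq_8h, n),
                   smoking = rep_len(smoking, n),
                   drinking = rep_len(drinking, n),
                   stringsAsFactors = FALSE)
  df$cne <- compute_cne(df$leq_8h, pmax(df$exposure_time, 0.01))
  for (f in NIHL_FREQUENCIES) {
    df[[paste0("L_", f)]] <- ht
    df[[paste0("R_", f)]] <- ht_right
  }
  cohort(df)
}

# set one ear/frequency column explicitly
set_ht <- function(x, col, values) {
  df <- as.data.frame(x)
  df[[col]] <- values
  cohort(df, frequencies = cohort_frequencies(x))
}

.cohort_cache <- new.env(parent = emptyenv())

shared_cohort <- function(name = "default6000") {
  if (!is.null(.cohort_cache[[name]])) return(.cohort_cache[[name]])
  x <- switch(name,
    default6000 = {
      p <- sim_params(n_workers = 6000, seed = 7)
      apply_study_exclusions(
        generate_preemployment(generate_cohort(p), p, 0.03))$cohort
    },
    stop("unknown shared cohort: ", name))
  .cohort_cache[[name]] <- x
  x
}

# Independent brute-force oracle: ids of the k highest / lowest values,
# ties broken by id (plain sort, no package code).
oracle_extremes <- function(ids, score, k) {
  o <- order(score, ids)
  list(low = ids[o][seq_len(k)], high = rev(ids[rev(o)][seq_len(k)]))
}
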