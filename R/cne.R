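#' Cumulative noise exposure (CNE)
#'
#' Equal-energy dose metric for occupational noise:
#' \deqn{CNE = L_{eq,8h} + 10 \log_{10}(T)}
#' where `leq_8h` is the equivalent continuous A-weighted sound level
#' normalized to an 8-hour workday (dBA) and `exposure_time` is the career
#' length T in years. A tenfold duration adds 10 dB, consistent with the
#' equal-energy principle; the logarithm is base 10 (the occupational-noise
#' convention).
#'
#' @param leq_8h dBA, vectorized.
#' @param exposure_time years, strictly positive, vectorized.
#' @return CNE in dBA-years.
#' @examples
#' compute_cne(85, 10)  # 95
#' @export
compute_cne <- function(leq_8h, exposure_time) {
  if (!is.numeric(leq_8h) || !is.numeric(exposure_time))
    stop("leq_8h and exposure_time must be numeric")
  if (any(!is.finite(exposure_time)) || any(exposure_time <= 0))
    stop("exposure_time must be finite and > 0")
  leq_8h + 10 * log10(exposure_time)
}
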