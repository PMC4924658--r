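#' Simulate a survival table with a group-dependent hazard
#'
#' Samples are split evenly into low- and high-expression groups; event
#' times are exponential with hazard `baseline_hazard` for the low group
#' and `baseline_hazard * hazard_ratio` for the high group. Censoring
#' times are independent exponentials whose rate is set per-subject so the
#' expected censored fraction equals `censor_rate` (`0` disables
#' censoring). Expression values are drawn so a median split recovers the
#' planted groups.
#'
#' @param n Number of samples (>= 2).
#' @param hazard_ratio Hazard of the high-expression group relative to the
#'   low group; > 0.
#' @param baseline_hazard Events per month in the low group; > 0.
#' @param censor_rate Expected censored fraction, in \[0, 1).
#' @param seed Integer RNG seed.
#'
#' @return A list with `table` (tibble: sample_id, time, event,
#'   expression) and `truth` (tibble: sample_id, group in high/low).
#' @export
simulate_survival <- function(n, hazard_ratio = 1, baseline_hazard = 0.05,
                              censor_rate = 0.2, seed = 1L) {
  if (n < 2) abort("`n` must be >= 2.")
  if (hazard_ratio <= 0) abort("`hazard_ratio` must be > 0.")
  if (baseline_hazard <= 0) abort("`baseline_hazard` must be > 0.")
  if (censor_rate < 0 || censor_rate >= 1) abort("`censor_rate` must lie in [0, 1).")
  with_seed(seed, {
    high <- rep(c(FALSE, TRUE), length.out = n)
    hz <- baseline_hazard * ifelse(high, hazard_ratio, 1)
    t_event <- rexp(n, rate = hz)
    if (censor_rate > 0) {
      c_rate <- hz * censor_rate / (1 - censor_rate)
      t_cens <- rexp(n, rate = c_rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    expression <- rnorm(n, mean = ifelse(high, 2, 0), sd = 0.5)
    list(
      table = tibble(sample_id = sprintf("S%04d", seq_len(n)),
                     time = time, event = event, expression = expression),
      truth = tibble(sample_id = sprintf("S%04d", seq_len(n)),
                     group = ifelse(high, "high", "low")))
  })
}
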