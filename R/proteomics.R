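#' Paired t-test over matched control/treated protein abundances
#'
#' For each protein, takes the per-pair differences `d_j = control_j -
#' treated_j` (log2 scale), the paired t statistic
#' `t = mean(d) / (sd(d) / sqrt(n))`, and the two-sided p-value on
#' `n - 1` degrees of freedom. The regulated pattern follows the
#' difference's sign: a negative control-minus-treated difference means
#' the protein is higher under treatment, i.e. "up". Proteins with any
#' missing value are excluded (listed in the `excluded` attribute);
#' zero-variance differences give p = 1 when the mean difference is also
#' zero and are otherwise flagged as the p -> 0 limit.
#'
#' @param table Data frame with a `protein` column and matched
#'   `control_1..k` / `treated_1..k` columns (k >= 2), log2 abundances.
#' @return A tibble (protein, t_diff, t_stat, p, pattern, degenerate)
#'   in input order; `t_diff` is the mean control - treated difference.
#' @export
paired_t <- function(table) {
  table <- as_tibble(table)
  ctrl_cols <- grep("^control_", names(table), value = TRUE)
  trt_cols <- grep("^treated_", names(table), value = TRUE)
  suffix <- function(v, prefix) as.integer(sub(prefix, "", v))
  ctrl_cols <- ctrl_cols[order(suffix(ctrl_cols, "control_"))]
  trt_cols <- trt_cols[order(suffix(trt_cols, "treated_"))]
  if (length(ctrl_cols) != length(trt_cols) ||
      !identical(suffix(ctrl_cols, "control_"), suffix(trt_cols, "treated_"))) {
    abort("Control and treated columns must come in complete matched pairs.")
  }
  n <- length(ctrl_cols)
  if (n < 2) abort("Need >= 2 pairs; the paired t-test is undefined otherwise.")
  ctrl <- as.matrix(table[, ctrl_cols])
  trt <- as.matrix(table[, trt_cols])
  d <- ctrl - trt
  ok <- complete.cases(d)
  excluded <- table$protein[!ok]
  d <- d[ok, , drop = FALSE]
  md <- rowMeans(d)
  sdd <- apply(d, 1, sd)
  t_stat <- ifelse(sdd > 0, md / (sdd / sqrt(n)), NA_real_)
  p <- ifelse(sdd > 0, 2 * pt(abs(t_stat), df = n - 1, lower.tail = FALSE),
              ifelse(md == 0, 1, 0))
  degenerate <- sdd == 0 & md != 0
  out <- tibble(protein = table$protein[ok], t_diff = md,
                t_stat = ifelse(sdd > 0, t_stat, ifelse(md == 0, 0, Inf * sign(md))),
                p = p,
                pattern = dplyr::case_when(md < 0 ~ "up",
                                           md > 0 ~ "down",
                                           TRUE ~ NA_character_),
                degenerate = degenerate)
  attr(out, "excluded") <- excluded
  out
}

#' Keep significantly regulated proteins
#'
#' @param results Output of [paired_t()].
#' @param alpha Significance threshold on the two-sided p (classic
#'   setting 0.001).
#' @return The rows with `p < alpha`, sorted by ascending p then protein
#'   id — ready to use as network seeds.
#' @export
filter_significant <- function(results, alpha = 0.001) {
  results |>
    dplyr::filter(.data$p < alpha) |>
    dplyr::arrange(.data$p, .data$protein)
}
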