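#' Split samples into high/low expression groups at the median
#'
#' The high group is everything strictly above the median; samples at or
#' below it (including all ties with the median) go to the low group.
#'
#' @param table Data frame with at least an `expression` column.
#' @return The input tibble with an added `expr_group` column
#'   (`"high"`/`"low"`); errors when expression is constant (no split
#'   exists).
#' @export
median_split <- function(table) {
  table <- as_tibble(table)
  if (!"expression" %in% names(table)) abort("`table` needs an `expression` column.")
  e <- table$expression
  if (length(unique(e)) < 2) abort("Expression is constant; cannot median-split.")
  med <- median(e)
  dplyr::mutate(table, expr_group = dplyr::if_else(e > med, "high", "low"))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator over the distinct event times:
#' `S(t_i) = prod_{j <= i} (1 - d_j / n_j)` with `n_j` at risk and `d_j`
#' events at `t_j`; purely censored times only deplete the risk sets.
#' Estimation goes through the standard survival machinery
#' ([survival::survfit()]).
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @return An object of class `km_curve`: tibble (time, n_risk, n_event,
#'   surv) restricted to event times, with the full survfit object as
#'   attribute `fit`.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0) abort("Empty input.")
  if (length(times) != length(events)) abort("`times` and `events` lengths differ.")
  if (any(times <= 0)) abort("All times must be positive.")
  if (!all(events %in% c(0, 1))) abort("`events` must be 0/1.")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  sm <- summary(fit, censored = FALSE)
  out <- if (length(sm$time) == 0) {
    tibble(time = numeric(0), n_risk = numeric(0), n_event = numeric(0),
           surv = numeric(0))
  } else {
    tibble(time = sm$time, n_risk = as.numeric(sm$n.risk),
           n_event = as.numeric(sm$n.event), surv = sm$surv)
  }
  out <- out[out$n_event > 0, , drop = FALSE]
  attr(out, "fit") <- fit
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank (Mantel-Cox) comparison
#'
#' Chi-square statistic `(sum(O - E))^2 / sum(V)` over the distinct event
#' times, with expectations and hypergeometric variances from the pooled
#' risk sets, referred to a chi-square with 1 degree of freedom
#' (via [survival::survdiff()]).
#'
#' @param group_a,group_b Data frames with `time` and `event` columns.
#' @return A list of class `logrank_result` with `chi2` and `p`.
#' @export
logrank <- function(group_a, group_b) {
  ga <- as_tibble(group_a)
  gb <- as_tibble(group_b)
  if (sum(ga$event) + sum(gb$event) == 0) {
    abort("No events in either group; log-rank undefined.")
  }
  df <- dplyr::bind_rows(dplyr::mutate(ga, .grp = "a"),
                         dplyr::mutate(gb, .grp = "b"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ .grp, data = df)
  chi2 <- unname(sd$chisq)
  structure(list(chi2 = chi2,
                 p = pchisq(chi2, df = 1, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi2 = %.4f, p = %.4g\n", x$chi2, x$p))
  invisible(x)
}

#' @describeIn logrank One-row tibble with `chi2` and `p`.
#' @param x A `logrank_result`.
#' @param ... Unused.
#' @exportS3Method generics::glance
#' @export
glance.logrank_result <- function(x, ...) tibble(chi2 = x$chi2, p = x$p)

#' Pearson correlation with a two-sided test
#'
#' Sample correlation of two expression vectors, with the usual
#' `t = r sqrt((n - 2) / (1 - r^2))` two-sided test
#' (via [stats::cor.test()]).
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @return A one-row tibble (r, p, n).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` lengths differ.")
  if (length(x) < 3) abort("Need at least 3 observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("Constant vector; correlation undefined.")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Median-split survival analysis of one gene
#'
#' Splits a survival table at the median expression, fits a Kaplan-Meier
#' curve per group and compares them by the log-rank test — the standard
#' prognostic read-out for a candidate driver.
#'
#' @param table Data frame with `time`, `event`, `expression` columns.
#' @return A list of class `km_comparison`: `curves` (named list of
#'   `km_curve`), `logrank` (`logrank_result`), `groups` (the split
#'   table).
#' @export
survival_by_median <- function(table) {
  split_tab <- median_split(table)
  hi <- dplyr::filter(split_tab, .data$expr_group == "high")
  lo <- dplyr::filter(split_tab, .data$expr_group == "low")
  list(curves = list(high = km_curve(hi$time, hi$event),
                     low = km_curve(lo$time, lo$event)),
       logrank = logrank(hi, lo),
       groups = split_tab) |>
    structure(class = "km_comparison")
}

#' @export
print.km_comparison <- function(x, ...) {
  n <- table(x$groups$expr_group)
  cat("<km_comparison> high n =", n[["high"]], "/ low n =", n[["low"]], "\n")
  print(x$logrank)
  invisible(x)
}

#' Kaplan-Meier step curves for a median-split comparison
#'
#' @param object A `km_comparison` from [survival_by_median()].
#' @param ... Unused.
#' @return A ggplot with one step curve per expression group and the
#'   log-rank p in the subtitle.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.km_comparison <- function(object, ...) {
  df <- purrr::imap_dfr(object$curves, function(cv, nm) {
    dplyr::bind_rows(tibble(time = 0, surv = 1),
                     tibble(time = cv$time, surv = cv$surv)) |>
      dplyr::mutate(group = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  colour = "expression",
                  subtitle = sprintf("log-rank p = %.3g", object$logrank$p)) +
    ggplot2::theme_minimal()
}
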