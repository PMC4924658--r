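#' SAM-style moderated statistics for one or many label assignments
#'
#' Given a genes x samples matrix and one or more 0/1 case-indicator
#' columns, computes per gene the numerator (case mean minus control
#' mean), the pooled standard error of that difference, and the damped
#' statistic d = numerator / (s + s0). Vectorised over assignments so the
#' permutation machinery reuses it.
#' @noRd
sam_d_matrix <- function(mat, X, s0) {
  X <- as.matrix(X)
  n1 <- colSums(1 - X)
  n2 <- colSums(X)
  mat2 <- mat^2
  S1 <- mat %*% (1 - X)
  S2 <- mat %*% X
  Q1 <- mat2 %*% (1 - X)
  Q2 <- mat2 %*% X
  m1 <- sweep(S1, 2, n1, "/")
  m2 <- sweep(S2, 2, n2, "/")
  ss <- pmax(Q1 - sweep(m1^2, 2, n1, "*") + Q2 - sweep(m2^2, 2, n2, "*"), 0)
  fac <- (1 / n1 + 1 / n2) / (n1 + n2 - 2)
  s <- sqrt(sweep(ss, 2, fac, "*"))
  num <- m2 - m1
  list(num = num, s = s, d = num / (s + s0))
}

#' SAM statistic per gene
#'
#' Computes the moderated two-class statistic
#' `d = (mean_case - mean_control) / (s + s0)` with `s` the pooled
#' standard error of the group-mean difference, plus the linear-scale fold
#' change `2^(mean_case - mean_control)` (inputs are log2).
#'
#' @param mat Numeric matrix, genes x samples, log2 scale.
#' @param groups Per-sample labels, `"control"`/`"case"` (character or
#'   factor); each group needs >= 2 samples.
#' @param s0 Exchangeability constant; if `NULL`, chosen by [choose_s0()].
#'
#' @return A tibble (gene, numerator, s, d, fold_change) with the used
#'   `s0` as an attribute.
#' @export
sam_score <- function(mat, groups, s0 = NULL) {
  groups <- as.character(groups)
  if (!all(groups %in% c("control", "case"))) {
    abort("`groups` must contain only \"control\" and \"case\".")
  }
  if (sum(groups == "control") < 2 || sum(groups == "case") < 2) {
    abort("Each group needs >= 2 samples.")
  }
  x <- matrix(as.numeric(groups == "case"), ncol = 1)
  raw <- sam_d_matrix(mat, x, s0 = 0)
  s <- raw$s[, 1]
  num <- raw$num[, 1]
  if (is.null(s0)) s0 <- choose_s0(s, num)
  num <- unname(num)
  s <- unname(s)
  out <- tibble(gene = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                numerator = num, s = s, d = num / (s + s0),
                fold_change = 2^num)
  attr(out, "s0") <- s0
  out
}

#' Choose the SAM exchangeability constant s0
#'
#' Evaluates candidate values of s0 at percentiles of the per-gene scatter
#' `s` and picks the one minimising the coefficient of variation of the
#' median absolute deviation of `d = num / (s + s0)` across windows of
#' the `s` distribution — the tuning that makes the variance of `d`
#' roughly independent of `s`.
#'
#' @param s Per-gene pooled scatter (>= 10 values).
#' @param num Per-gene numerators (same length).
#' @param percentiles Candidate percentiles of `s` (defaults to 0, 5, ...,
#'   100 percent).
#'
#' @return The chosen s0 (a single number). If every `s` is zero, returns
#'   0 with a warning.
#' @export
choose_s0 <- function(s, num, percentiles = seq(0, 1, by = 0.05)) {
  if (length(s) < 10) abort("Need >= 10 genes to tune s0.")
  if (all(s == 0)) {
    warn("All per-gene scatters are zero; s0 = 0.")
    return(0)
  }
  cand <- quantile(s, percentiles, names = FALSE, type = 7)
  nw <- max(3, min(100, floor(length(s) / 10)))
  # quantile windows of s; ties collapse windows, which is fine
  br <- unique(quantile(s, seq(0, 1, length.out = nw + 1), names = FALSE))
  win <- if (length(br) > 2) {
    cut(s, br, include.lowest = TRUE)
  } else {
    factor(rep(1L, length(s)))
  }
  cv <- vapply(cand, function(s0) {
    d <- num / (s + s0)
    mads <- tapply(d, win, mad)
    mads <- mads[is.finite(mads)]
    m <- mean(mads)
    if (!is.finite(m) || m == 0) return(Inf)
    sd(mads) / m
  }, numeric(1))
  if (all(!is.finite(cv))) return(cand[1])
  cand[which.min(cv)]
}

#' SAM permutation analysis with FDR-controlled calling
#'
#' Scores genes with the SAM statistic, builds the permutation null by
#' recomputing d under permuted group labels (full enumeration of the
#' `choose(n, n_control)` distinct assignments whenever that count fits in
#' `B`, otherwise `B` random draws), and compares the ordered observed
#' statistics with the expected order statistics `d_bar`. A gene is called
#' at threshold `delta` when `|d - d_bar| >= delta` at its rank and its
#' fold change passes `max(fc, 1/fc) >= fc_cutoff`. The FDR is the median,
#' over permutations, of the number of permuted statistics beyond the
#' d-scale calling cutpoints, divided by the number of called genes and
#' clipped to \[0, 1\].
#'
#' When `delta` is `NULL` it is chosen automatically as the smallest value
#' on a grid of step 0.05 whose estimated FDR is at most `fdr_cutoff`.
#'
#' @inheritParams sam_score
#' @param delta Calling threshold on the |d - d_bar| scale, or `NULL` to
#'   choose automatically.
#' @param fdr_cutoff Target FDR for the automatic delta choice
#'   (default 0.05).
#' @param fc_cutoff Symmetric fold-change filter (default 1.2).
#' @param B Permutation budget (default 200); with `choose(n, n_control)
#'   <= B` all distinct assignments are enumerated and the result does not
#'   depend on `seed`.
#' @param seed RNG seed for the sampled-permutation path.
#'
#' @return An object of class `sam_fit`; see [tidy.sam_fit()] and
#'   [glance.sam_fit()].
#' @export
sam_permutation <- function(mat, groups, delta = NULL, fdr_cutoff = 0.05,
                            fc_cutoff = 1.2, B = 200L, seed = 1L) {
  if (B < 1) abort("`B` must be >= 1.")
  groups <- as.character(groups)
  scores <- sam_score(mat, groups)
  s0 <- attr(scores, "s0")
  n <- length(groups)
  n_ctl <- sum(groups == "control")

  n_distinct <- choose(n, n_ctl)
  enumerated <- is.finite(n_distinct) && n_distinct <= B
  X <- if (enumerated) {
    combos <- combn(n, n_ctl)
    apply(combos, 2, function(idx) as.numeric(!(seq_len(n) %in% idx)))
  } else {
    with_seed(seed, {
      replicate(B, as.numeric(sample(groups) == "case"))
    })
  }
  d_perm <- sam_d_matrix(mat, X, s0)$d
  d_perm_sorted <- apply(d_perm, 2, sort)
  d_bar <- rowMeans(d_perm_sorted)

  # deterministic rank: d ascending, gene id breaks ties
  ord <- order(scores$d, scores$gene)
  d_sorted <- scores$d[ord]

  eval_delta <- function(dl) {
    sig_rank <- abs(d_sorted - d_bar) >= dl
    fc <- scores$fold_change[ord]
    pass_fc <- pmax(fc, 1 / fc) >= fc_cutoff
    called_rank <- sig_rank & pass_fc
    up_d <- d_sorted[sig_rank & d_sorted > 0]
    down_d <- d_sorted[sig_rank & d_sorted < 0]
    cut_up <- if (length(up_d)) min(up_d) else Inf
    cut_low <- if (length(down_d)) max(down_d) else -Inf
    n_called <- sum(called_rank)
    fdr <- if (n_called == 0) 0 else {
      false_counts <- colSums(d_perm >= cut_up | d_perm <= cut_low)
      min(1, median(false_counts) / n_called)
    }
    list(called_rank = called_rank, n_called = n_called, fdr = fdr,
         cut_up = cut_up, cut_low = cut_low)
  }

  if (is.null(delta)) {
    grid <- seq(0, max(abs(d_sorted - d_bar)) + 0.05, by = 0.05)
    delta <- grid[length(grid)]
    for (dl in grid) {
      if (eval_delta(dl)$fdr <= fdr_cutoff) {
        delta <- dl
        break
      }
    }
  }
  res <- eval_delta(delta)

  called <- logical(nrow(scores))
  called[ord] <- res$called_rank
  out <- scores
  out$d_bar <- NA_real_
  out$d_bar[ord] <- d_bar
  out$called <- called
  out$direction <- dplyr::if_else(out$d >= 0, "up", "down")
  out$fdr <- res$fdr
  structure(list(scores = out, s0 = s0, delta = delta, fdr = res$fdr,
                 n_called = res$n_called, cut_up = res$cut_up,
                 cut_low = res$cut_low, B = ncol(X),
                 enumerated = enumerated, fc_cutoff = fc_cutoff),
            class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("<sam_fit> ", nrow(x$scores), " genes; s0 = ", signif(x$s0, 4),
      "; delta = ", x$delta, "; called = ", x$n_called,
      " (est. FDR ", signif(x$fdr, 3), ")\n", sep = "")
  invisible(x)
}

#' Per-gene SAM results as a tibble
#'
#' @param x A `sam_fit` from [sam_permutation()].
#' @param ... Unused.
#' @return A tibble with one row per gene: observed statistic `d`,
#'   scatter `s`, expected order statistic `d_bar` at the gene's rank,
#'   fold change, call flag, direction and the threshold-level FDR.
#' @exportS3Method generics::tidy
#' @export
tidy.sam_fit <- function(x, ...) x$scores

#' One-row summary of a SAM fit
#' @inheritParams tidy.sam_fit
#' @exportS3Method generics::glance
#' @export
glance.sam_fit <- function(x, ...) {
  tibble(s0 = x$s0, delta = x$delta, fdr = x$fdr, n_called = x$n_called,
         n_permutations = x$B, enumerated = x$enumerated)
}

#' SAM quantile plot (observed vs expected order statistics)
#'
#' @param object A `sam_fit`.
#' @param ... Unused.
#' @return A ggplot: observed d against expected d_bar, the identity line,
#'   the delta band, and called genes coloured by direction.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.sam_fit <- function(object, ...) {
  df <- object$scores |>
    dplyr::arrange(.data$d, .data$gene) |>
    dplyr::mutate(status = dplyr::if_else(
      .data$called, paste0("called ", .data$direction), "not called"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_bar, y = .data$d,
                                   colour = .data$status)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = c(-1, 1) * object$delta,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      "called up" = "#c0392b", "called down" = "#1e8449",
      "not called" = "grey55")) +
    ggplot2::labs(x = "expected order statistic",
                  y = "observed d", colour = NULL) +
    ggplot2::theme_minimal()
}
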