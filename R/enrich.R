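#' Right-tailed Fisher exact probability of a gene-set overlap
#'
#' Probability, under the hypergeometric null, of drawing at least `x`
#' pathway genes when `n` signature genes are sampled from a universe of
#' `N` genes of which `K` belong to the pathway:
#' `p = sum_{i >= x} C(K, i) C(N - K, n - i) / C(N, n)`. Evaluated through
#' the hypergeometric distribution function, which works in log space, so
#' it is stable for large counts. The right tail includes the observation,
#' so `x = 0` gives exactly 1.
#'
#' @param x Observed overlap count.
#' @param n Signature size within the universe.
#' @param K Pathway size within the universe.
#' @param N Universe size.
#' @return The upper-tail probability, in (0, 1].
#' @export
fisher_right_tail <- function(x, n, K, N) {
  if (any(c(x, n, K, N) < 0) || n > N || K > N || x > min(n, K)) {
    abort("Inconsistent counts: need 0 <= x <= min(n, K) and n, K <= N.")
  }
  phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway over-representation of a gene signature
#'
#' Scores every pathway by the right-tailed Fisher exact test against a
#' fixed gene universe (by default, the genes of the integrated matrix).
#' Signature and pathway members outside the universe are dropped before
#' counting; dropped signature genes are reported via an attribute.
#'
#' @param signature Character vector of signature gene ids.
#' @param pathways Named list of gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of all assayable gene ids.
#' @return A tibble of class `enrichment_result` (pathway, x, n, K, N,
#'   p_right, p_adj), sorted by ascending p then pathway id; `p_adj` is
#'   Benjamini-Hochberg across pathways. Attribute `dropped_signature`
#'   lists signature genes outside the universe.
#' @export
enrich <- function(signature, pathways, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  if (length(pathways) == 0) abort("`pathways` must be non-empty.")
  sig_all <- unique(as.character(signature))
  dropped <- setdiff(sig_all, universe)
  sig <- intersect(sig_all, universe)
  N <- length(universe)
  n <- length(sig)
  out <- purrr::imap_dfr(pathways, function(members, nm) {
    mem <- intersect(unique(members), universe)
    K <- length(mem)
    x <- length(intersect(sig, mem))
    tibble(pathway = nm, x = x, n = n, K = K, N = N,
           p_right = fisher_right_tail(x, n, K, N))
  }) |>
    dplyr::mutate(p_adj = p.adjust(.data$p_right, method = "BH")) |>
    dplyr::arrange(.data$p_right, .data$pathway)
  attr(out, "dropped_signature") <- dropped
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Enrichment bar plot
#'
#' @param object An `enrichment_result`.
#' @param top Number of pathways to show (default 15).
#' @param ... Unused.
#' @return A ggplot of -log10 adjusted p per pathway.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.enrichment_result <- function(object, top = 15, ...) {
  df <- head(as_tibble(object), top) |>
    dplyr::mutate(pathway = stats::reorder(.data$pathway, -.data$p_adj))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_adj),
                                   y = .data$pathway)) +
    ggplot2::geom_col(fill = "#2e86c1") +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL) +
    ggplot2::theme_minimal()
}
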