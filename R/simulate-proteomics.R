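#' Simulate a paired protein-abundance table
#'
#' Emulates a matched vehicle/treated replicate design on the log2 scale:
#' per-protein baselines, a shared per-pair (replicate) effect that makes
#' pairing informative, a planted treatment shift on `shifted_proteins`
#' proteins (alternating up/down in the treated condition), and Gaussian
#' residual noise.
#'
#' @param n_proteins Number of proteins.
#' @param n_pairs Number of matched control/treated pairs (>= 2; the
#'   paired t-test is undefined below that).
#' @param shifted_proteins Number of proteins given the planted shift
#'   (<= `n_proteins`).
#' @param shift Absolute planted shift in log2 units.
#' @param noise_sd Residual SD, > 0.
#' @param seed Integer RNG seed.
#'
#' @return A list with `table` (tibble: protein, control_1..k,
#'   treated_1..k) and `truth` (tibble: protein, pattern in up/down — the
#'   direction in the treated condition).
#' @export
simulate_paired_proteomics <- function(n_proteins, n_pairs = 3,
                                       shifted_proteins = 0, shift = 0,
                                       noise_sd = 0.3, seed = 1L) {
  if (n_pairs < 2) abort("`n_pairs` must be >= 2 (paired t undefined).")
  if (shifted_proteins > n_proteins) {
    abort("`shifted_proteins` must be <= `n_proteins`.")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  with_seed(seed, {
    prot <- sprintf("PROT%05d", seq_len(n_proteins))
    base <- rnorm(n_proteins, 25, 2)
    pair_eff <- matrix(rnorm(n_proteins * n_pairs, 0, 0.5), n_proteins)
    eff <- numeric(n_proteins)
    idx <- seq_len(shifted_proteins)
    if (shifted_proteins > 0) {
      eff[idx] <- rep(c(1, -1), length.out = shifted_proteins) * shift
    }
    ctrl <- base + pair_eff +
      matrix(rnorm(n_proteins * n_pairs, 0, noise_sd), n_proteins)
    trt <- base + pair_eff + eff +
      matrix(rnorm(n_proteins * n_pairs, 0, noise_sd), n_proteins)
    colnames(ctrl) <- paste0("control_", seq_len(n_pairs))
    colnames(trt) <- paste0("treated_", seq_len(n_pairs))
    tab <- dplyr::bind_cols(tibble(protein = prot), as_tibble(ctrl),
                            as_tibble(trt))
    truth <- tibble(protein = prot[idx],
                    pattern = ifelse(eff[idx] > 0, "up", "down"))
    list(table = tab, truth = truth)
  })
}
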