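#' Run code under a local RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their arguments and do not perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the multi-study expression simulator
#'
#' Defaults emulate the integrated three-study case/control design the
#' pipeline was built around: three studies with (control, case) counts
#' (10, 10), (5, 12) and (11, 16), a planted differential-expression
#' fraction of 5% at 1.5 log2 fold change, additive and multiplicative
#' batch effects, and Gaussian residual noise.
#'
#' @param n_studies Number of studies (batches).
#' @param n_control,n_case Integer vectors of per-study group sizes,
#'   recycled to `n_studies`.
#' @param n_genes Number of genes.
#' @param de_fraction Fraction of genes with a planted group effect, in
#'   \[0, 1\].
#' @param log2_fc Planted absolute group effect in log2 units; direction is
#'   split 50/50 up/down.
#' @param batch_shift_sd SD of the per-batch-per-gene additive shift
#'   (log2 units).
#' @param batch_scale_sd Dispersion of the per-batch-per-gene multiplicative
#'   noise-scale factor (lognormal with unit mean; 0 disables).
#' @param noise_sd Residual SD (log2 units), > 0.
#' @param baseline_mean,baseline_sd Distribution of per-gene baselines.
#' @param seed Integer RNG seed.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_studies = 3,
                              n_control = c(10L, 5L, 11L),
                              n_case = c(10L, 12L, 16L),
                              n_genes = 2000,
                              de_fraction = 0.05,
                              log2_fc = 1.5,
                              batch_shift_sd = 1,
                              batch_scale_sd = 0.25,
                              noise_sd = 0.5,
                              baseline_mean = 7,
                              baseline_sd = 1,
                              seed = 1L) {
  n_control <- rep_len(as.integer(n_control), n_studies)
  n_case <- rep_len(as.integer(n_case), n_studies)
  cfg <- list(n_studies = as.integer(n_studies), n_control = n_control,
              n_case = n_case, n_genes = as.integer(n_genes),
              de_fraction = de_fraction, log2_fc = log2_fc,
              batch_shift_sd = batch_shift_sd,
              batch_scale_sd = batch_scale_sd, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  if (cfg$n_studies < 1 || cfg$n_genes < 1 ||
      any(n_control < 1) || any(n_case < 1)) {
    abort("All study, sample and gene counts must be >= 1.")
  }
  if (de_fraction < 0 || de_fraction > 1) abort("`de_fraction` must lie in [0, 1].")
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  if (batch_shift_sd < 0 || batch_scale_sd < 0) {
    abort("Batch effect scales must be >= 0.")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a multi-study case/control expression cohort
#'
#' Generates one cohort per study under the additive/multiplicative batch
#' model `y = alpha_g + beta_g x_j + gamma_{sg} + delta_{sg} eps_{gj}`:
#' per-gene baselines `alpha_g`, a group effect `beta_g` of `+/- log2_fc`
#' for the planted DE genes (zero otherwise), Gaussian per-batch additive
#' shifts `gamma`, lognormal unit-mean multiplicative dispersions `delta`,
#' and Gaussian residuals. This is exactly the model the parametric
#' empirical-Bayes batch correction assumes, so correction quality is
#' testable by parameter recovery.
#'
#' @param config A [simulation_config()].
#'
#' @return A list with elements:
#' \describe{
#'   \item{cohorts}{named list of per-study `expression_cohort`s}
#'   \item{cohort}{the merged `expression_cohort` (shared genes, batch =
#'     study)}
#'   \item{truth}{list with `de_genes` (tibble: gene, direction, beta),
#'     `gamma` and `delta` (batch x gene matrices of the planted effects)}
#' }
#' @export
simulate_multistudy_expression <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    ng <- config$n_genes
    genes <- sprintf("G%05d", seq_len(ng))
    n_de <- round(config$de_fraction * ng)
    de_idx <- if (n_de > 0) sort(sample.int(ng, n_de)) else integer(0)
    beta <- numeric(ng)
    if (n_de > 0) {
      # 50/50 up/down so direction-consistency logic gets exercised
      dir_up <- rep(c(TRUE, FALSE), length.out = n_de)
      dir_up <- sample(dir_up)
      beta[de_idx] <- ifelse(dir_up, config$log2_fc, -config$log2_fc)
    }
    alpha <- rnorm(ng, config$baseline_mean, config$baseline_sd)

    studies <- paste0("study", seq_len(config$n_studies))
    gamma <- matrix(rnorm(config$n_studies * ng, 0, config$batch_shift_sd),
                    nrow = config$n_studies,
                    dimnames = list(studies, genes))
    if (config$batch_scale_sd > 0) {
      delta <- matrix(rlnorm(config$n_studies * ng,
                             meanlog = -config$batch_scale_sd^2 / 2,
                             sdlog = config$batch_scale_sd),
                      nrow = config$n_studies,
                      dimnames = list(studies, genes))
    } else {
      delta <- matrix(1, nrow = config$n_studies, ncol = ng,
                      dimnames = list(studies, genes))
    }

    cohorts <- vector("list", config$n_studies)
    names(cohorts) <- studies
    for (s in seq_len(config$n_studies)) {
      nc <- config$n_control[s]
      nk <- config$n_case[s]
      n <- nc + nk
      x <- c(rep(0, nc), rep(1, nk))
      eps <- matrix(rnorm(ng * n, 0, config$noise_sd), nrow = ng)
      mat <- alpha + outer(beta, x) + gamma[s, ] + delta[s, ] * eps
      ids <- sprintf("%s_%s%02d", studies[s],
                     c(rep("ctl", nc), rep("cas", nk)),
                     c(seq_len(nc), seq_len(nk)))
      dimnames(mat) <- list(genes, ids)
      cohorts[[s]] <- expression_cohort(
        mat,
        tibble(sample_id = ids, batch = studies[s],
               group = c(rep("control", nc), rep("case", nk))))
    }
    merged <- if (config$n_studies >= 2) merge_cohorts(cohorts) else cohorts[[1]]
    truth <- list(
      de_genes = tibble(gene = genes[de_idx],
                        direction = ifelse(beta[de_idx] > 0, "up", "down"),
                        beta = beta[de_idx]),
      gamma = gamma, delta = delta, alpha = setNames(alpha, genes),
      beta = setNames(beta, genes))
    list(cohorts = cohorts, cohort = merged, truth = truth)
  })
}
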