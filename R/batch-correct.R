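#' Standardize a cohort for empirical-Bayes batch modelling
#'
#' Fits the gene-wise location model `y_gj = alpha_g + beta_g x_j +
#' batch effects + error` by least squares on a design holding one
#' indicator per batch plus the case/control covariate, takes the grand
#' mean `alpha_g` as the batch-size-weighted average of the batch
#' coefficients, and standardizes to
#' `z_gj = (y_gj - alpha_g - beta_g x_j) / sigma_g`, with `sigma_g` the
#' root mean squared residual (divisor N). The group covariate is
#' protected: its fitted effect is removed before batch estimation and
#' re-added after correction, so biological signal is not absorbed into
#' the batch model. Zero-variance genes get a floored `sigma_g` (1e-8)
#' and are flagged.
#'
#' @param cohort An `expression_cohort` with >= 1 batch.
#'
#' @return A list of class `standardized_cohort`: `z` (standardized
#'   matrix), `alpha`, `beta`, `sigma` (per-gene vectors), `flagged`
#'   (gene ids with floored sigma), `batch`, `x` (0/1 case indicator),
#'   `sample_ids`.
#' @export
fit_standardization <- function(cohort) {
  stopifnot(inherits(cohort, "expression_cohort"))
  y <- cohort$exprs
  batch <- factor(cohort$samples$batch)
  x <- as.numeric(cohort$samples$group == "case")
  n <- ncol(y)
  if (any(table(batch) < 2)) abort("Each batch must contain >= 2 samples.")

  bat_design <- stats::model.matrix(~ 0 + batch)
  design <- cbind(bat_design, case = x)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    # a batch perfectly confounded with group: drop the covariate
    design <- bat_design
    x_used <- FALSE
  } else {
    x_used <- TRUE
  }
  # gene-wise OLS, all genes at once
  bhat <- t(solve(crossprod(design), crossprod(design, t(y))))
  nb <- nlevels(batch)
  wts <- as.numeric(table(batch)) / n
  alpha <- as.numeric(bhat[, seq_len(nb), drop = FALSE] %*% wts)
  beta <- if (x_used) bhat[, nb + 1] else rep(0, nrow(y))
  fitted <- tcrossprod(bhat, design)
  sigma2 <- rowMeans((y - fitted)^2)
  sigma <- sqrt(sigma2)
  flagged <- rownames(y)[sigma < 1e-8]
  sigma[sigma < 1e-8] <- 1e-8

  z <- (y - alpha - outer(beta, x)) / sigma
  z[sigma <= 1e-8, ] <- 0
  structure(list(z = z, alpha = setNames(alpha, rownames(y)),
                 beta = setNames(beta, rownames(y)),
                 sigma = setNames(sigma, rownames(y)),
                 flagged = flagged, batch = batch, x = x,
                 sample_ids = colnames(y)),
            class = "standardized_cohort")
}

# method-of-moments hyperpriors for the inverse-gamma dispersion prior
ig_moments <- function(delta_hat) {
  m <- mean(delta_hat)
  s2 <- var(delta_hat)
  if (!is.finite(s2) || s2 <= 0) s2 <- 1e-8
  list(lambda = (2 * s2 + m^2) / s2, theta = (m * s2 + m^3) / s2)
}

#' Empirical-Bayes shrinkage of per-batch effects
#'
#' Estimates, per batch, a normal prior on the per-gene additive batch
#' effects (`gamma_bar`, `tau2`) and an inverse-gamma prior on the
#' per-gene multiplicative dispersions (`lambda`, `theta`) by the method
#' of moments, then solves for the shrunken effects `(gamma_star,
#' delta_star)` by the standard iterative conditional update until the
#' largest absolute change falls below `tol`.
#'
#' @param std A `standardized_cohort` from [fit_standardization()], or a
#'   standardized numeric matrix (genes x samples) if `batch` is given.
#' @param batch Per-sample batch labels; only needed when `std` is a bare
#'   matrix.
#' @param tol Convergence tolerance on the largest absolute parameter
#'   change (default 1e-4).
#' @param max_iter Iteration cap (default 200); non-convergence raises an
#'   error of class `consignet_convergence_error` carrying the last
#'   iterate.
#'
#' @return An object of class `batch_model` with batch x gene matrices
#'   `gamma_hat`, `delta_hat`, `gamma_star`, `delta_star`, per-batch
#'   hyperparameters `gamma_bar`, `tau2`, `lambda`, `theta`, and (when
#'   `std` came from [fit_standardization()]) the standardization
#'   parameters `alpha`, `beta`, `sigma` needed by [apply_correction()].
#' @export
eb_shrink <- function(std, batch = NULL, tol = 1e-4, max_iter = 200L) {
  if (inherits(std, "standardized_cohort")) {
    z <- std$z
    batch <- std$batch
  } else {
    z <- std
    if (is.null(batch)) abort("`batch` is required when `std` is a matrix.")
    std <- NULL
    batch <- factor(batch)
  }
  batch <- factor(batch)
  if (any(table(batch) < 2)) abort("Each batch must contain >= 2 samples.")
  levs <- levels(batch)
  ng <- nrow(z)
  genes <- rownames(z) %||% as.character(seq_len(ng))

  dims <- list(levs, genes)
  gamma_hat <- delta_hat <- gamma_star <- delta_star <-
    matrix(NA_real_, length(levs), ng, dimnames = dims)
  gamma_bar <- tau2 <- lambda <- theta <- setNames(numeric(length(levs)), levs)
  n_iter <- setNames(integer(length(levs)), levs)

  for (i in seq_along(levs)) {
    zi <- z[, batch == levs[i], drop = FALSE]
    ni <- ncol(zi)
    g_hat <- rowMeans(zi)
    d_hat <- apply(zi, 1, var)
    d_hat[d_hat < 1e-12] <- 1e-12
    gb <- mean(g_hat)
    t2 <- var(g_hat)
    if (!is.finite(t2) || t2 <= 0) t2 <- 1e-8
    hp <- ig_moments(d_hat)

    g_old <- g_hat
    d_old <- d_hat
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- (ni * t2 * g_hat + d_old * gb) / (ni * t2 + d_old)
      sum2 <- rowSums((zi - g_new)^2)
      d_new <- (hp$theta + 0.5 * sum2) / (ni / 2 + hp$lambda - 1)
      change <- max(abs(g_new - g_old), abs(d_new - d_old))
      g_old <- g_new
      d_old <- d_new
      if (change < tol) break
      if (it >= max_iter) {
        abort(sprintf("EB update did not converge in %d iterations (last change %.3g).",
                      max_iter, change),
              class = "consignet_convergence_error",
              gamma_star = g_old, delta_star = d_old)
      }
    }
    gamma_hat[i, ] <- g_hat
    delta_hat[i, ] <- d_hat
    gamma_star[i, ] <- g_old
    delta_star[i, ] <- d_old
    gamma_bar[i] <- gb
    tau2[i] <- t2
    lambda[i] <- hp$lambda
    theta[i] <- hp$theta
    n_iter[i] <- it
  }
  structure(list(batches = levs, genes = genes,
                 gamma_hat = gamma_hat, delta_hat = delta_hat,
                 gamma_star = gamma_star, delta_star = delta_star,
                 gamma_bar = gamma_bar, tau2 = tau2,
                 lambda = lambda, theta = theta, n_iter = n_iter,
                 alpha = std$alpha, beta = std$beta, sigma = std$sigma),
            class = "batch_model")
}

#' @export
print.batch_model <- function(x, ...) {
  cat("<batch_model> ", length(x$batches), " batch(es) x ",
      length(x$genes), " genes\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @describeIn eb_shrink Per-batch-per-gene effect estimates as a tibble
#'   (`batch`, `gene`, `gamma_hat`, `gamma_star`, `delta_hat`,
#'   `delta_star`).
#' @param x A `batch_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.batch_model <- function(x, ...) {
  tidyr::expand_grid(batch = x$batches, gene = x$genes) |>
    dplyr::mutate(gamma_hat = as.vector(t(x$gamma_hat)),
                  gamma_star = as.vector(t(x$gamma_star)),
                  delta_hat = as.vector(t(x$delta_hat)),
                  delta_star = as.vector(t(x$delta_star)))
}

#' @describeIn eb_shrink Per-batch prior hyperparameters and iteration
#'   counts.
#' @exportS3Method generics::glance
#' @export
glance.batch_model <- function(x, ...) {
  tibble(batch = x$batches, gamma_bar = unname(x$gamma_bar),
         tau2 = unname(x$tau2), lambda = unname(x$lambda),
         theta = unname(x$theta), n_iter = unname(x$n_iter))
}

#' Apply an empirical-Bayes batch correction to a cohort
#'
#' Transforms each value by removing the shrunken additive batch effect
#' and dividing out the shrunken dispersion on the standardized scale,
#' then restores the per-gene scale, baseline and group effect:
#' `y*_gj = sigma_g / sqrt(delta_star) * (z_gj - gamma_star) + alpha_g +
#' beta_g x_j`.
#'
#' @param cohort The `expression_cohort` to correct (genes must match the
#'   model).
#' @param model A `batch_model` from [eb_shrink()] run on a
#'   `standardized_cohort` (so it carries `alpha`, `beta`, `sigma`).
#'
#' @return The corrected `expression_cohort`, same dimensions as the
#'   input.
#' @export
apply_correction <- function(cohort, model) {
  stopifnot(inherits(cohort, "expression_cohort"),
            inherits(model, "batch_model"))
  if (is.null(model$alpha)) {
    abort("`model` lacks standardization parameters; fit via fit_standardization().")
  }
  if (!identical(rownames(cohort$exprs), model$genes)) {
    abort("Gene sets of cohort and model do not match.")
  }
  batch <- as.character(cohort$samples$batch)
  if (!all(batch %in% model$batches)) {
    abort("Cohort contains batches absent from the model.")
  }
  x <- as.numeric(cohort$samples$group == "case")
  y <- cohort$exprs
  z <- (y - model$alpha - outer(model$beta, x)) / model$sigma
  bi <- match(batch, model$batches)
  # per-sample columns of the batch x gene effect matrices
  gam <- t(model$gamma_star)[, bi, drop = FALSE]
  del <- t(model$delta_star)[, bi, drop = FALSE]
  corrected <- model$sigma / sqrt(del) * (z - gam) + model$alpha +
    outer(model$beta, x)
  dimnames(corrected) <- dimnames(y)
  expression_cohort(corrected, cohort$samples)
}

#' One-step empirical-Bayes batch correction
#'
#' Convenience wrapper: standardize, shrink, apply. A single-batch cohort
#' is returned unchanged with a null model (`gamma_star = 0`,
#' `delta_star = 1`) — there is nothing to correct.
#'
#' @inheritParams eb_shrink
#' @param cohort An `expression_cohort`.
#' @return A list with `cohort` (corrected) and `model` (`batch_model`).
#' @export
correct_batch_effects <- function(cohort, tol = 1e-4, max_iter = 200L) {
  stopifnot(inherits(cohort, "expression_cohort"))
  levs <- unique(as.character(cohort$samples$batch))
  if (length(levs) < 2) {
    genes <- rownames(cohort$exprs)
    dims <- list(levs, genes)
    null_model <- structure(
      list(batches = levs, genes = genes,
           gamma_hat = matrix(0, 1, length(genes), dimnames = dims),
           delta_hat = matrix(1, 1, length(genes), dimnames = dims),
           gamma_star = matrix(0, 1, length(genes), dimnames = dims),
           delta_star = matrix(1, 1, length(genes), dimnames = dims),
           gamma_bar = setNames(0, levs), tau2 = setNames(0, levs),
           lambda = setNames(NA_real_, levs), theta = setNames(NA_real_, levs),
           n_iter = setNames(0L, levs),
           alpha = NULL, beta = NULL, sigma = NULL),
      class = "batch_model")
    return(list(cohort = cohort, model = null_model))
  }
  std <- fit_standardization(cohort)
  model <- eb_shrink(std, tol = tol, max_iter = max_iter)
  list(cohort = apply_correction(cohort, model), model = model)
}

#' Mean absolute per-gene batch contrast
#'
#' Diagnostic used to quantify residual batch signal: for each gene, the
#' gap between one batch's mean and the mean over all other batches'
#' samples, averaged in absolute value over genes.
#'
#' @param cohort An `expression_cohort`.
#' @param batch_label Which batch to contrast against the rest (default:
#'   the first).
#' @return A single non-negative number.
#' @export
batch_contrast <- function(cohort, batch_label = NULL) {
  stopifnot(inherits(cohort, "expression_cohort"))
  b <- as.character(cohort$samples$batch)
  batch_label <- batch_label %||% unique(b)[1]
  inb <- b == batch_label
  if (!any(inb) || all(inb)) abort("`batch_label` must split the samples.")
  mean(abs(rowMeans(cohort$exprs[, inb, drop = FALSE]) -
             rowMeans(cohort$exprs[, !inb, drop = FALSE])))
}
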