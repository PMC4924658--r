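test_that("merging intersects gene sets and concatenates samples", {
  mk <- function(genes, prefix, batch) {
    m <- matrix(rnorm(length(genes) * 4), nrow = length(genes),
                dimnames = list(genes, paste0(prefix, 1:4)))
    expression_cohort(m, data.frame(
      sample_id = colnames(m), batch = batch,
      group = rep(c("control", "case"), each = 2)))
  }
  a <- mk(c("A", "B", "C"), "a", "s1")
  b <- mk(c("B", "C", "D"), "b", "s2")
  merged <- merge_cohorts(list(s1 = a, s2 = b))
  expect_identical(rownames(merged$exprs), c("B", "C"))
  expect_equal(ncol(merged$exprs), 8)

  expect_error(merge_cohorts(list(a, mk(c("X", "Y"), "x", "s3"))), "shared")
  expect_error(merge_cohorts(list(a, mk(c("A", "B"), "a", "s3"))), "Duplicate")
})

test_that("merged synthetic cohorts keep the generator's shared-gene count", {
  sim <- make_test_cohort(seed = 5)
  sub <- lapply(names(sim$cohorts), function(nm) {
    co <- sim$cohorts[[nm]]
    keep <- switch(nm,
                   study1 = 1:250, study2 = 51:300, study3 = 1:300)
    expression_cohort(co$exprs[keep, , drop = FALSE], co$samples)
  })
  names(sub) <- names(sim$cohorts)
  merged <- merge_cohorts(sub)
  expect_equal(nrow(merged$exprs), 200)  # genes 51..250 shared by all three
})

test_that("standardization recovers the group effect and centres residuals", {
  sim <- simulate_multistudy_expression(
    simulation_config(n_genes = 2000, seed = 8))
  std <- fit_standardization(sim$cohort)
  de <- sim$truth$de_genes
  recovered <- std$beta[de$gene] * ifelse(de$direction == "up", 1, -1)
  expect_equal(mean(recovered), 1.5, tolerance = 0.15)
  expect_lt(max(abs(rowMeans(std$z))), 1e-8)
})

test_that("balanced two-batch toy with equal group means gives beta = 0", {
  vals <- c(1, 2, 1, 2, 3, 4, 3, 4)  # same control/case means in both batches
  m <- matrix(rep(vals, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:8)))
  co <- expression_cohort(m, data.frame(
    sample_id = colnames(m), batch = rep(c("b1", "b2"), each = 4),
    group = rep(c("control", "control", "case", "case"), 2)))
  std <- fit_standardization(co)
  expect_equal(unname(std$beta), c(0, 0), tolerance = 1e-12)
})

test_that("constant genes are sigma-floored with zero standardized values", {
  sim <- make_test_cohort(seed = 2, n_genes = 50)
  co <- sim$cohort
  co$exprs[1, ] <- 5
  std <- fit_standardization(co)
  expect_identical(std$flagged, rownames(co$exprs)[1])
  expect_true(all(std$z[1, ] == 0))
})

test_that("EB shrinkage pulls batch effects toward the prior mean", {
  sim <- simulate_multistudy_expression(
    simulation_config(n_genes = 2000, de_fraction = 0, batch_shift_sd = 0,
                      batch_scale_sd = 0, seed = 21))
  std <- fit_standardization(sim$cohort)
  model <- eb_shrink(std)
  expect_lt(mean(abs(model$gamma_star)), mean(abs(model$gamma_hat)))
  expect_true(all(model$delta_star > 0))
})

test_that("a batch identical to the rest gets a near-zero shrunken effect", {
  set.seed(4)
  z <- matrix(rnorm(400), nrow = 20)
  rownames(z) <- sprintf("g%02d", 1:20)
  z <- z - rowMeans(z)
  model <- eb_shrink(z, batch = rep(c("b1", "b2"), each = 10))
  expect_lt(mean(abs(model$gamma_star)), mean(abs(rowMeans(z))) + 0.1)
  expect_lt(abs(mean(model$gamma_star["b2", ])), 0.1)
})

test_that("a planted additive shift is recovered on the standardized scale", {
  sim <- simulate_multistudy_expression(
    simulation_config(n_genes = 2000, de_fraction = 0, batch_shift_sd = 0,
                      batch_scale_sd = 0, seed = 31))
  co <- sim$cohort
  in2 <- co$samples$batch == "study2"
  co$exprs[, in2] <- co$exprs[, in2] + 2
  std <- fit_standardization(co)
  model <- eb_shrink(std)
  w2 <- mean(in2)
  truth_std <- mean(2 * (1 - w2) / std$sigma)
  expect_equal(mean(model$gamma_star["study2", ]), truth_std, tolerance = 0.1)
})

test_that("correction removes planted shifts and reduces batch F-statistics", {
  sim <- simulate_multistudy_expression(
    simulation_config(n_genes = 2000, de_fraction = 0, batch_shift_sd = 0,
                      batch_scale_sd = 0, seed = 41))
  co <- sim$cohort
  in2 <- co$samples$batch == "study2"
  co$exprs[, in2] <- co$exprs[, in2] + 2
  expect_equal(batch_contrast(co, "study2"), 2, tolerance = 0.1)
  fixed <- correct_batch_effects(co)
  expect_lt(batch_contrast(fixed$cohort, "study2"), 0.1)

  mean_batch_f <- function(cohort) {
    b <- factor(cohort$samples$batch)
    mean(apply(cohort$exprs, 1, function(y) {
      anova(lm(y ~ b))[["F value"]][1]
    }))
  }
  drops <- vapply(1:5, function(s) {
    sim <- simulate_multistudy_expression(
      simulation_config(n_genes = 100, batch_shift_sd = 1, seed = s))
    fixed <- correct_batch_effects(sim$cohort)
    mean_batch_f(fixed$cohort) < mean_batch_f(sim$cohort)
  }, logical(1))
  expect_true(all(drops))
})

test_that("single-batch cohorts pass through correction unchanged", {
  sim <- make_test_cohort(seed = 6, n_genes = 50)
  solo <- sim$cohorts$study1
  out <- correct_batch_effects(solo)
  expect_equal(out$cohort$exprs, solo$exprs, tolerance = 1e-8)
})

test_that("correction preserves group contrasts and is near-idempotent", {
  # no additive batch effect, so the naive before/after group contrast is
  # not contaminated by batch leakage and preservation is testable directly
  sim <- simulate_multistudy_expression(
    simulation_config(n_genes = 1000, batch_shift_sd = 0, seed = 51))
  grp <- sim$cohort$samples$group
  gdiff <- function(co) rowMeans(co$exprs[, grp == "case"]) -
    rowMeans(co$exprs[, grp == "control"])
  once <- correct_batch_effects(sim$cohort)
  expect_lt(mean(abs(gdiff(once$cohort) - gdiff(sim$cohort))), 0.1)
  expect_identical(dim(once$cohort$exprs), dim(sim$cohort$exprs))

  # under the default design (with batch effects) the corrected contrast
  # still tracks the planted biology
  sim2 <- simulate_multistudy_expression(
    simulation_config(n_genes = 1000, seed = 52))
  fixed2 <- correct_batch_effects(sim2$cohort)$cohort
  beta_true <- sim2$truth$beta[rownames(fixed2$exprs)]
  grp2 <- fixed2$samples$group
  gd2 <- rowMeans(fixed2$exprs[, grp2 == "case"]) -
    rowMeans(fixed2$exprs[, grp2 == "control"])
  expect_lt(mean(abs(gd2 - beta_true)), 0.15)

  twice <- correct_batch_effects(once$cohort)
  first_change <- mean(abs(once$cohort$exprs - sim$cohort$exprs))
  second_change <- mean(abs(twice$cohort$exprs - once$cohort$exprs))
  expect_lt(second_change, first_change)
  # a second pass moves values by no more than (a small multiple of) the
  # residual batch signal the first pass left behind
  residual <- mean(vapply(unique(once$cohort$samples$batch),
                          function(b) batch_contrast(once$cohort, b),
                          numeric(1)))
  expect_lt(second_change, 10 * residual)
})

test_that("shrunken estimates agree with the reference EB implementation", {
  skip_if_not_installed("sva")
  sim <- simulate_multistudy_expression(
    simulation_config(n_genes = 500, seed = 61))
  co <- sim$cohort
  fixed <- correct_batch_effects(co)$cohort
  mod <- stats::model.matrix(~ group, data = co$samples)
  ref <- sva::ComBat(dat = co$exprs, batch = co$samples$batch, mod = mod)
  # same model, same priors: corrected values should track closely
  expect_lt(mean(abs(fixed$exprs - ref)), 0.05)
  expect_gt(cor(as.vector(fixed$exprs), as.vector(ref)), 0.999)
})
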