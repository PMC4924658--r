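test_that("expression simulation is deterministic and books its truth", {
  a <- simulate_multistudy_expression(simulation_config(n_genes = 200, seed = 1))
  b <- simulate_multistudy_expression(simulation_config(n_genes = 200, seed = 1))
  expect_identical(a$cohort$exprs, b$cohort$exprs)
  expect_identical(a$truth$de_genes, b$truth$de_genes)

  cfg <- simulation_config(n_genes = 2000, de_fraction = 0.05, log2_fc = 1.5)
  sim <- simulate_multistudy_expression(cfg)
  expect_equal(nrow(sim$truth$de_genes), 100)
  expect_true(all(sim$truth$de_genes$gene %in% rownames(sim$cohort$exprs)))
  expect_setequal(unique(sim$truth$de_genes$direction), c("up", "down"))
  # batch labels match the study of origin
  expect_identical(sort(unique(sim$cohort$samples$batch)),
                   paste0("study", 1:3))
})

test_that("null expression simulation has centred group contrasts", {
  sim <- simulate_multistudy_expression(
    simulation_config(n_genes = 2000, de_fraction = 0, batch_shift_sd = 0,
                      batch_scale_sd = 0, seed = 42))
  grp <- sim$cohort$samples$group
  diffs <- rowMeans(sim$cohort$exprs[, grp == "case"]) -
    rowMeans(sim$cohort$exprs[, grp == "control"])
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("planted DE genes carry the requested effect in expectation", {
  sim <- simulate_multistudy_expression(
    simulation_config(n_genes = 2000, batch_shift_sd = 0,
                      batch_scale_sd = 0, seed = 3))
  grp <- sim$cohort$samples$group
  diffs <- rowMeans(sim$cohort$exprs[, grp == "case"]) -
    rowMeans(sim$cohort$exprs[, grp == "control"])
  up <- sim$truth$de_genes$gene[sim$truth$de_genes$direction == "up"]
  expect_equal(mean(diffs[up]), 1.5, tolerance = 0.1)
})

test_that("expression simulation rejects invalid configurations", {
  expect_error(simulation_config(n_genes = 0), "counts")
  expect_error(simulation_config(de_fraction = 1.2), "de_fraction")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
})

test_that("simulated interaction networks are simple with planted hubs", {
  a <- simulate_ppi(50, 3, seed = 7)
  b <- simulate_ppi(50, 3, seed = 7)
  expect_identical(a$edges, b$edges)

  expect_true(all(a$edges$node_a != a$edges$node_b))
  expect_false(any(duplicated(paste(a$edges$node_a, a$edges$node_b))))

  big <- simulate_ppi(500, 5, attachment = 2, seed = 11)
  deg <- table(c(big$edges$node_a, big$edges$node_b))
  q90 <- quantile(as.numeric(deg), 0.9)
  expect_true(all(deg[big$truth$hub_seeds] >= q90))
  expect_error(simulate_ppi(10, 10), "n_seed_hubs")
})

test_that("simulated pathways respect closure and planted overlap", {
  genes <- sprintf("G%03d", 1:300)
  pw <- simulate_pathways(genes, n_sets = 10, seed = 5)
  expect_length(pw$sets, 10)
  expect_true(all(unlist(pw$sets) %in% genes))
  expect_identical(pw$sets, simulate_pathways(genes, n_sets = 10, seed = 5)$sets)

  sig <- genes[1:15]
  full <- simulate_pathways(genes, n_sets = 5, set_size_range = c(20, 30),
                            enriched_fraction = 1, signature = sig, seed = 2)
  expect_true(all(sig %in% full$sets$planted_set))
  expect_error(simulate_pathways(character(0)), "non-empty")
})

test_that("survival simulation honours censoring and hazard ordering", {
  sv <- simulate_survival(100, hazard_ratio = 2, censor_rate = 0, seed = 1)
  expect_true(all(sv$table$event == 1L))

  wins <- vapply(1:20, function(s) {
    sv <- simulate_survival(200, hazard_ratio = 3, censor_rate = 0, seed = s)
    joined <- merge(sv$table, sv$truth, by = "sample_id")
    median(joined$time[joined$group == "high"]) <
      median(joined$time[joined$group == "low"])
  }, logical(1))
  expect_gt(mean(wins), 0.5)
  expect_error(simulate_survival(100, hazard_ratio = 0), "hazard_ratio")
})

test_that("paired proteomics simulation is reproducible and null-calibrated", {
  a <- simulate_paired_proteomics(50, seed = 9)
  expect_identical(a$table, simulate_paired_proteomics(50, seed = 9)$table)
  expect_error(simulate_paired_proteomics(50, n_pairs = 1), "n_pairs")

  null <- simulate_paired_proteomics(2000, n_pairs = 3, shifted_proteins = 0,
                                     shift = 0, seed = 13)
  res <- paired_t(null$table)
  expect_lte(mean(res$p < 0.001), 0.005)
})

test_that("power at an extreme planted shift matches the noncentral-t law", {
  # with 3 pairs the paired t has 2 df; even at shift 4 and noise 0.1 the
  # detection power is the exact noncentral-t tail, not 1
  sim <- simulate_paired_proteomics(200, n_pairs = 3, shifted_proteins = 100,
                                    shift = 4, noise_sd = 0.1, seed = 17)
  hits <- filter_significant(paired_t(sim$table), alpha = 0.001)
  observed <- mean(sim$truth$protein %in% hits$protein)
  sd_diff <- sqrt(2) * 0.1
  ncp <- 4 / (sd_diff / sqrt(3))
  crit <- qt(1 - 0.001 / 2, df = 2)
  power <- pt(crit, df = 2, ncp = ncp, lower.tail = FALSE) +
    pt(-crit, df = 2, ncp = ncp)
  expect_lt(abs(observed - power), 4 * sqrt(power * (1 - power) / 100))
  # and none of the unshifted proteins sneak in
  expect_lte(mean(setdiff(sim$table$protein, sim$truth$protein) %in%
                    hits$protein), 0.005)
})
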