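#' Default pipeline parameters
#' @noRd
default_params <- function() {
  list(k = 8L, m = 6L, fdr = 0.05, fc = 1.2, B = 200L, alpha = 0.001,
       order = 1L, mode = "mixed", seed = 1L)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)),
          class = "consignet_stage_error", stage = stage)
  })
}

#' Run the full signature-and-network pipeline
#'
#' Sequences the whole analysis: read per-study matrices, merge on shared
#' genes, empirical-Bayes batch correction, virtual-dataset consensus
#' differential expression, paired-t proteomics filtering, seed-network
#' construction with cleaning / topology / root ranking / Steiner
#' reduction, pathway enrichment of the robust signatures, and
#' median-split survival. Every stage writes its table under
#' `config$out_dir` and the run ends with a `manifest.yaml` recording
#' parameters, seeds and per-stage sizes.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `matrices` (character vector of expression TSV paths, one per
#'   study), `annotation` (annotation TSV), `edges` (character vector of
#'   SIF/TSV edge files), `gmt` (pathway GMT), `proteomics` (paired
#'   abundance TSV), `survival` (survival TSV), `out_dir`, and an
#'   optional `params` list overriding `k`, `m`, `fdr`, `fc`, `B`,
#'   `alpha`, `order`, `mode`, `seed`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  params <- modifyList(default_params(), config$params %||% list())
  out_dir <- config$out_dir %||% abort("`config$out_dir` is required.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("consignet")),
                   params = params, stages = list())

  # --- integrate ------------------------------------------------------
  merged <- run_stage("integrate", {
    for (p in c(config$matrices, config$annotation)) {
      if (!file.exists(p)) abort(paste0("Input not found: ", p))
    }
    ann <- readr::read_tsv(config$annotation, show_col_types = FALSE)
    if ("study_id" %in% names(ann) && !"batch" %in% names(ann)) {
      ann$batch <- ann$study_id
    }
    cohorts <- lapply(config$matrices, function(mp) {
      df <- readr::read_tsv(mp, show_col_types = FALSE)
      mat <- as.matrix(df[, -1, drop = FALSE])
      rownames(mat) <- as.character(df[[1]])
      sub <- ann[ann$sample_id %in% colnames(mat), c("sample_id", "batch", "group")]
      expression_cohort(mat, sub)
    })
    names(cohorts) <- vapply(cohorts, function(co) co$samples$batch[1],
                             character(1))
    merged <- if (length(cohorts) >= 2) merge_cohorts(cohorts) else cohorts[[1]]
    corrected <- correct_batch_effects(merged)
    write_cohort(corrected$cohort, file.path(out_dir, "merged.tsv"),
                 file.path(out_dir, "merged_annotation.tsv"))
    corrected$cohort
  })
  manifest$stages$integrate <- list(genes = nrow(merged$exprs),
                                    samples = ncol(merged$exprs))

  # --- consensus differential expression ------------------------------
  consensus <- run_stage("consensus_de", {
    res <- run_consensus_de(merged, k = params$k, m = params$m,
                            mode = params$mode, fdr_cutoff = params$fdr,
                            fc_cutoff = params$fc, B = params$B,
                            seed = params$seed)
    readr::write_tsv(res$signatures, file.path(out_dir, "signatures.tsv"))
    res
  })
  robust <- consensus$signatures$gene[consensus$signatures$robust]
  manifest$stages$consensus_de <- list(virtual_datasets = length(consensus$fits),
                                       robust_signatures = length(robust))

  # --- proteomics seeds -----------------------------------------------
  seeds <- run_stage("proteomics", {
    tab <- readr::read_tsv(config$proteomics, show_col_types = FALSE)
    res <- paired_t(tab)
    sig <- filter_significant(res, alpha = params$alpha)
    readr::write_tsv(sig, file.path(out_dir, "seed_proteins.tsv"))
    sig
  })
  manifest$stages$proteomics <- list(proteins_tested = nrow(seeds) +
                                       length(attr(seeds, "excluded") %||% character(0)),
                                     seeds = nrow(seeds))

  # --- network ---------------------------------------------------------
  net <- run_stage("network", {
    interactions <- load_interactions(config$edges)
    network <- build_seed_network(interactions, seeds$protein,
                                  order = params$order) |>
      clean_network()
    topo <- node_topology(network)
    roots <- rank_roots(network)
    readr::write_tsv(topo, file.path(out_dir, "node_topology.tsv"))
    readr::write_tsv(roots, file.path(out_dir, "root_ranking.tsv"))
    write_sif(tidy_edges(network), file.path(out_dir, "network.sif"))
    terminals <- intersect(seeds$protein, igraph::V(network$graph)$name)
    st <- steiner_tree(network, terminals)
    readr::write_tsv(tidy(st), file.path(out_dir, "steiner_edges.tsv"))
    list(network = network, topology = topo, roots = roots, steiner = st)
  })
  manifest$stages$network <- list(nodes = igraph::vcount(net$network$graph),
                                  edges = igraph::ecount(net$network$graph),
                                  top_root = net$roots$node[1],
                                  steiner_cost = net$steiner$cost)

  # --- enrichment ------------------------------------------------------
  enr <- run_stage("enrichment", {
    sets <- read_gmt(config$gmt)
    res <- enrich(robust, sets, universe = rownames(merged$exprs))
    readr::write_tsv(as_tibble(res), file.path(out_dir, "enrichment.tsv"))
    res
  })
  manifest$stages$enrichment <- list(pathways = nrow(enr),
                                     top_pathway = enr$pathway[1])

  # --- survival --------------------------------------------------------
  surv <- run_stage("survival", {
    tab <- readr::read_tsv(config$survival, show_col_types = FALSE)
    cmp <- survival_by_median(tab)
    curves <- purrr::imap_dfr(cmp$curves, function(cv, nm) {
      dplyr::mutate(as_tibble(cv), group = nm)
    })
    readr::write_tsv(curves, file.path(out_dir, "km_curves.tsv"))
    readr::write_tsv(glance(cmp$logrank), file.path(out_dir, "logrank.tsv"))
    cmp
  })
  manifest$stages$survival <- list(n = nrow(surv$groups),
                                   logrank_p = surv$logrank$p)

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

tidy_edges <- function(network) {
  el <- igraph::as_edgelist(network$graph)
  tibble(node_a = pmin(el[, 1], el[, 2]), node_b = pmax(el[, 1], el[, 2]))
}

#' Generate demo fixtures and run the whole pipeline on them
#'
#' Writes every synthetic input (expression matrices, annotation, edge
#' tables, GMT, paired proteomics, survival) under `dir/inputs`, runs
#' [run_pipeline()] on them, and returns the manifest plus the planted
#' ground truth so recovery can be checked.
#'
#' @param dir Output directory.
#' @param seed Master seed; every stage seed derives from it.
#' @param n_genes,n_nodes Demo problem sizes (kept modest so the demo
#'   runs in well under five minutes on one CPU).
#' @param B Permutation budget for the SAM stage.
#' @return Invisibly, a list with `manifest`, `truth`, `config`.
#' @export
run_demo <- function(dir = tempfile("consignet_demo_"), seed = 1L,
                     n_genes = 800L, n_nodes = 800L, B = 100L) {
  inputs <- file.path(dir, "inputs")
  dir.create(inputs, recursive = TRUE, showWarnings = FALSE)

  sim <- simulate_multistudy_expression(
    simulation_config(n_genes = n_genes, seed = seed))
  mat_paths <- character(0)
  ann_all <- list()
  for (nm in names(sim$cohorts)) {
    mp <- file.path(inputs, paste0(nm, ".tsv"))
    write_cohort(sim$cohorts[[nm]], mp, file.path(inputs, paste0(nm, "_ann.tsv")))
    mat_paths <- c(mat_paths, mp)
    ann_all[[nm]] <- sim$cohorts[[nm]]$samples
  }
  ann <- dplyr::bind_rows(ann_all)
  readr::write_tsv(tibble(sample_id = ann$sample_id, study_id = ann$batch,
                          group = ann$group),
                   file.path(inputs, "annotation.tsv"))

  ppi <- simulate_ppi(n_nodes, n_seed_hubs = 17, attachment = 2,
                      seed = seed + 1)
  # split the edge table across two source files to exercise the union
  half <- seq_len(nrow(ppi$edges) %/% 2)
  e1 <- file.path(inputs, "interactions_a.sif")
  e2 <- file.path(inputs, "interactions_b.sif")
  write_sif(ppi$edges[half, ], e1)
  write_sif(ppi$edges[-half, ], e2)

  # paired proteomics whose shifted proteins are exactly the planted hubs
  n_prot <- min(300L, as.integer(n_nodes))
  prot <- simulate_paired_proteomics(n_proteins = n_prot, n_pairs = 3,
                                     shifted_proteins = 17, shift = 4,
                                     noise_sd = 0.1, seed = seed + 2)
  others <- with_seed(seed + 3, {
    sample(setdiff(sprintf("P%04d", seq_len(n_nodes)), ppi$truth$hub_seeds),
           n_prot - 17)
  })
  ids <- c(ppi$truth$hub_seeds, others)
  prot$table$protein <- ids
  prot$truth$protein <- ids[seq_len(17)]
  readr::write_tsv(prot$table, file.path(inputs, "proteomics.tsv"))

  pw <- simulate_pathways(rownames(sim$cohort$exprs), n_sets = 12,
                          signature = head(sim$truth$de_genes$gene, 25),
                          enriched_fraction = 0.8, seed = seed + 4)
  gmt_path <- file.path(inputs, "pathways.gmt")
  write_gmt(pw$sets, gmt_path)

  sv <- simulate_survival(n = 200, hazard_ratio = 3, baseline_hazard = 0.05,
                          censor_rate = 0.2, seed = seed + 5)
  readr::write_tsv(sv$table, file.path(inputs, "survival.tsv"))

  config <- list(matrices = mat_paths,
                 annotation = file.path(inputs, "annotation.tsv"),
                 edges = c(e1, e2), gmt = gmt_path,
                 proteomics = file.path(inputs, "proteomics.tsv"),
                 survival = file.path(inputs, "survival.tsv"),
                 out_dir = file.path(dir, "results"),
                 params = list(B = B, seed = seed))
  yaml::write_yaml(config, file.path(dir, "run.yaml"))
  manifest <- run_pipeline(config)
  invisible(list(manifest = manifest, config = config,
                 truth = list(expression = sim$truth, ppi = ppi$truth,
                              pathways = pw$truth, survival = sv$truth,
                              proteomics = prot$truth)))
}
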