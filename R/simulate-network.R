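#' Simulate a scale-free interaction network with planted hub seeds
#'
#' Grows a Barabasi-Albert preferential-attachment graph, then augments a
#' random subset of nodes with extra edges until each reaches at least the
#' graph's maximum initial degree, so the planted "seed" proteins sit in
#' the top tail of the degree distribution the way the pipeline's root
#' proteins do.
#'
#' @param n_nodes Number of nodes.
#' @param n_seed_hubs Number of planted high-degree seed nodes
#'   (< `n_nodes`).
#' @param attachment Edges added per node during preferential attachment;
#'   must be < `n_nodes`.
#' @param seed Integer RNG seed.
#'
#' @return A list with `edges` (tibble: node_a, node_b, source), an
#'   undirected simple edge table, and `truth` (list with `hub_seeds`, the
#'   planted hub node ids).
#' @export
simulate_ppi <- function(n_nodes, n_seed_hubs, attachment = 2, seed = 1L) {
  if (n_seed_hubs >= n_nodes) abort("`n_seed_hubs` must be < `n_nodes`.")
  if (attachment >= n_nodes) abort("`attachment` must be < `n_nodes`.")
  if (n_nodes < 2) abort("`n_nodes` must be >= 2.")
  with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = attachment, directed = FALSE)
    igraph::V(g)$name <- sprintf("P%04d", seq_len(n_nodes))
    g <- igraph::simplify(g)
    hubs <- sample(igraph::V(g)$name, n_seed_hubs)
    target <- max(igraph::degree(g))
    for (h in hubs) {
      need <- target - igraph::degree(g, h)
      if (need > 0) {
        candidates <- setdiff(igraph::V(g)$name,
                              c(h, names(igraph::neighbors(g, h))))
        pick <- sample(candidates, min(need, length(candidates)))
        g <- igraph::add_edges(g, as.vector(rbind(h, pick)))
      }
    }
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g)
    # canonical order within an undirected pair, then sorted rows
    a <- pmin(el[, 1], el[, 2])
    b <- pmax(el[, 1], el[, 2])
    o <- order(a, b)
    edges <- tibble(node_a = a[o], node_b = b[o], source = "simulated")
    list(edges = edges, truth = list(hub_seeds = sort(hubs)))
  })
}

#' Simulate pathway gene sets with one planted enriched set
#'
#' Draws `n_sets` random gene sets from `genes`; the first set is the
#' designated "enriched" pathway and is forced to contain the requested
#' fraction of a designated signature.
#'
#' @param genes Character vector of gene ids (the universe).
#' @param n_sets Number of gene sets.
#' @param set_size_range Length-2 integer vector, inclusive range of set
#'   sizes; sizes must not exceed `length(genes)`.
#' @param enriched_fraction Fraction of `signature` planted into the
#'   designated enriched set, in \[0, 1\].
#' @param signature Character vector of signature genes (subset of
#'   `genes`); defaults to the first `min(20, length(genes) %/% 10)` genes.
#' @param seed Integer RNG seed.
#'
#' @return A list with `sets` (named list of gene-id vectors; the planted
#'   set is named `"planted_set"`) and `truth` (list with `enriched_set`
#'   and `signature`).
#' @export
simulate_pathways <- function(genes, n_sets = 10, set_size_range = c(15, 60),
                              enriched_fraction = 0.8, signature = NULL,
                              seed = 1L) {
  if (length(genes) == 0) abort("`genes` must be non-empty.")
  if (max(set_size_range) > length(genes)) {
    abort("Set sizes cannot exceed the number of genes.")
  }
  if (is.null(signature)) {
    signature <- head(genes, max(1, min(20, length(genes) %/% 10)))
  }
  if (!all(signature %in% genes)) abort("`signature` must be a subset of `genes`.")
  with_seed(seed, {
    sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                    replace = TRUE)
    sets <- vector("list", n_sets)
    names(sets) <- c("planted_set", sprintf("random_set_%02d", seq_len(n_sets - 1)))
    n_in <- round(enriched_fraction * length(signature))
    planted <- sample(signature, n_in)
    size1 <- max(sizes[1], n_in)
    filler <- sample(setdiff(genes, planted), size1 - n_in)
    sets[[1]] <- sort(c(planted, filler))
    for (i in seq_len(n_sets)[-1]) {
      sets[[i]] <- sort(sample(genes, sizes[i]))
    }
    list(sets = sets,
         truth = list(enriched_set = "planted_set", signature = signature))
  })
}

#' Write gene sets as a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    abort("Reading GMT requires the fgsea package.")
  }
  fgsea::gmtPathways(path)
}
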