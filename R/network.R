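#' Build an interaction set from an edge table
#'
#' Canonicalises an undirected edge table: orders each pair, drops
#' self-loops (tallied), merges duplicate edges while concatenating their
#' source tags.
#'
#' @param edges Data frame with columns `node_a`, `node_b` and optionally
#'   `source`.
#' @return A tibble of class `interaction_set` (node_a <= node_b, one row
#'   per undirected edge, `source` holding `;`-joined tags) with attribute
#'   `n_self_loops_dropped`.
#' @export
as_interaction_set <- function(edges) {
  edges <- as_tibble(edges)
  if (!all(c("node_a", "node_b") %in% names(edges))) {
    abort("`edges` needs columns node_a and node_b.")
  }
  if (!"source" %in% names(edges)) edges$source <- "unknown"
  a <- as.character(edges$node_a)
  b <- as.character(edges$node_b)
  self <- a == b
  n_self <- sum(self)
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  out <- tibble(node_a = a2, node_b = b2, source = edges$source[!self]) |>
    tidyr::separate_rows("source", sep = ";") |>
    dplyr::distinct() |>
    dplyr::group_by(.data$node_a, .data$node_b) |>
    dplyr::summarise(source = paste(sort(unique(.data$source)), collapse = ";"),
                     .groups = "drop") |>
    dplyr::arrange(.data$node_a, .data$node_b)
  attr(out, "n_self_loops_dropped") <- n_self
  class(out) <- c("interaction_set", class(out))
  out
}

#' Load protein-interaction edge tables
#'
#' Reads one or more SIF (`nodeA<TAB>type<TAB>nodeB`) or two-column TSV
#' files, tags every edge with the file it came from, and unions them into
#' one deduplicated undirected interaction set.
#'
#' @param paths Character vector of file paths.
#' @return An `interaction_set`; see [as_interaction_set()].
#' @export
load_interactions <- function(paths) {
  if (length(paths) == 0) abort("`paths` must name at least one file.")
  tabs <- lapply(paths, function(p) {
    lines <- readLines(p)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (length(nf) == 0) abort(paste0("Empty edge file: ", p))
    # allow a header row on 2-column TSVs
    header <- nf[1] >= 2 && identical(tolower(parts[[1]][1]), "node_a")
    if (header) {
      parts <- parts[-1]
      nf <- nf[-1]
    }
    bad <- which(!(nf %in% c(2L, 3L)))
    if (length(bad) > 0) {
      abort(sprintf("Malformed line %d in %s: expected 2 or 3 tab-separated fields.",
                    bad[1] + header, p))
    }
    tibble(node_a = vapply(parts, `[[`, character(1), 1),
           node_b = vapply(parts, function(f) f[[length(f)]], character(1)),
           source = basename(p))
  })
  as_interaction_set(dplyr::bind_rows(tabs))
}

#' Write an interaction set as SIF
#'
#' @param interactions An `interaction_set`.
#' @param path Output path; edges written as `nodeA<TAB>pp<TAB>nodeB`.
#' @return Invisibly, `path`.
#' @export
write_sif <- function(interactions, path) {
  writeLines(paste(interactions$node_a, "pp", interactions$node_b,
                   sep = "\t"), path)
  invisible(path)
}

as_igraph <- function(interactions) {
  igraph::graph_from_data_frame(
    interactions[, c("node_a", "node_b")], directed = FALSE)
}

new_gene_network <- function(graph, report = list()) {
  structure(list(graph = graph, report = report), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  roles <- igraph::V(x$graph)$role
  cat("<gene_network> ", igraph::vcount(x$graph), " nodes (",
      sum(roles == "root"), " root) / ", igraph::ecount(x$graph),
      " edges\n", sep = "")
  if (length(x$report$missing_seeds)) {
    cat("  seeds absent from interaction universe: ",
        paste(x$report$missing_seeds, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Expand seed proteins into an interaction network
#'
#' Keeps the seeds found in the interaction universe plus every node
#' within `order` hops of any seed, with all interaction edges among the
#' retained nodes (induced expansion). Seeds become `root` nodes,
#' everything else `interactor`. Seeds absent from the universe are
#' silently omitted but listed in the network's report.
#'
#' @param interactions An `interaction_set` (or edge data frame).
#' @param seeds Character vector of seed node ids.
#' @param order Neighborhood order, 1 (direct interactors) or 2
#'   (indirect as well).
#' @return A `gene_network`.
#' @export
build_seed_network <- function(interactions, seeds, order = 1L) {
  if (!order %in% c(1L, 2L)) abort("`order` must be 1 or 2.")
  if (!inherits(interactions, "interaction_set")) {
    interactions <- as_interaction_set(interactions)
  }
  g <- as_igraph(interactions)
  present <- intersect(seeds, igraph::V(g)$name)
  missing <- setdiff(seeds, present)
  if (length(present) == 0) {
    abort("No seed is present in the interaction universe.",
          class = "consignet_empty_network_error")
  }
  hood <- igraph::ego(g, order = order, nodes = present)
  keep <- sort(unique(unlist(lapply(hood, names))))
  sub <- igraph::induced_subgraph(g, keep)
  igraph::V(sub)$role <- ifelse(igraph::V(sub)$name %in% present,
                                "root", "interactor")
  new_gene_network(sub, report = list(missing_seeds = missing))
}

#' Clean a network to its analysable core
#'
#' Removes self-loops and multi-edges, deletes unconnected nodes, and
#' keeps only the largest connected component (ties broken toward the
#' component containing the lexicographically smallest node id).
#'
#' @param network A `gene_network`.
#' @return The cleaned `gene_network`; errors if nothing survives.
#' @export
clean_network <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  g <- igraph::simplify(network$graph)
  deg <- igraph::degree(g)
  g <- igraph::delete_vertices(g, names(deg)[deg == 0])
  if (igraph::vcount(g) == 0) {
    abort("Network is empty after cleaning.",
          class = "consignet_empty_network_error")
  }
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    mins <- vapply(best, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, character(1))
    best <- best[order(mins)[1]]
  }
  keep <- igraph::V(g)$name[comp$membership == best]
  new_gene_network(igraph::induced_subgraph(g, keep),
                   report = network$report)
}

#' Per-node degree, neighbor-edge count and clustering coefficient
#'
#' For each node n: `k_n` the degree, `e_n` the number of edges among n's
#' neighbors, and the clustering coefficient
#' `CC = 2 e_n / (k_n (k_n - 1))`, set to 0 by convention when `k_n < 2`.
#'
#' @param network A `gene_network` (or a bare igraph graph).
#' @return A tibble (node, role, k_n, e_n, cc) sorted by node id.
#' @export
node_topology <- function(network) {
  g <- if (inherits(network, "gene_network")) network$graph else network
  nodes <- igraph::V(g)$name
  roles <- igraph::V(g)$role %||% rep(NA_character_, length(nodes))
  adj <- igraph::as_adj_list(g, mode = "all")
  deg <- igraph::degree(g)
  en <- vapply(seq_along(nodes), function(i) {
    nb <- names(adj[[i]])
    nb <- setdiff(unique(nb), nodes[i])
    if (length(nb) < 2) return(0)
    igraph::ecount(igraph::induced_subgraph(g, nb))
  }, numeric(1))
  cc <- unname(ifelse(deg >= 2, 2 * en / (deg * (deg - 1)), 0))
  tibble(node = nodes, role = roles, k_n = as.numeric(deg),
         e_n = en, cc = cc) |>
    dplyr::arrange(.data$node)
}

#' Rank root proteins by network topology
#'
#' Orders roots by descending degree, then ascending clustering
#' coefficient, then node id — high-degree hubs whose neighbors are not
#' interconnected rank first, the profile of a driver coordinating many
#' otherwise-unrelated partners.
#'
#' @param network A `gene_network`.
#' @param roots Root node ids; defaults to the network's `root`-role
#'   nodes. Roots absent from the network are omitted (listed in the
#'   `missing_roots` attribute).
#' @return A tibble (node, k_n, e_n, cc, rank).
#' @export
rank_roots <- function(network, roots = NULL) {
  stopifnot(inherits(network, "gene_network"))
  topo <- node_topology(network)
  if (is.null(roots)) roots <- topo$node[topo$role == "root"]
  missing <- setdiff(roots, topo$node)
  out <- topo |>
    dplyr::filter(.data$node %in% roots) |>
    dplyr::arrange(dplyr::desc(.data$k_n), .data$cc, .data$node) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("node", "k_n", "e_n", "cc", "rank")
  attr(out, "missing_roots") <- missing
  out
}

#' Match a gene signature into an interaction atlas
#'
#' Treats the signature genes as seeds, expands them one hop into the
#' atlas (induced edges included) and cleans the result to its largest
#' connected component.
#'
#' @param signature Character vector of gene ids.
#' @param interactions The atlas as an `interaction_set` (or edge data
#'   frame).
#' @param order Expansion order, 1 or 2.
#' @return A cleaned `gene_network`.
#' @export
match_signatures_to_atlas <- function(signature, interactions, order = 1L) {
  clean_network(build_seed_network(interactions, signature, order = order))
}

#' Degree/clustering profile plot for root proteins
#'
#' @param object A `gene_network`.
#' @param ... Unused.
#' @return A ggplot of k_n vs CC, roots highlighted and labelled.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.gene_network <- function(object, ...) {
  topo <- node_topology(object)
  roots <- dplyr::filter(topo, .data$role == "root")
  ggplot2::ggplot(topo, ggplot2::aes(x = .data$k_n, y = .data$cc)) +
    ggplot2::geom_point(colour = "grey60", size = 1) +
    ggplot2::geom_point(data = roots, colour = "#c0392b", size = 2) +
    ggplot2::geom_text(data = roots, ggplot2::aes(label = .data$node),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "degree k_n", y = "clustering coefficient CC") +
    ggplot2::theme_minimal()
}
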