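#' Steiner-tree reduction of a network (KMB approximation)
#'
#' Connects a set of terminal nodes by a small tree inside the network
#' using the classic metric-closure approximation: build the complete
#' graph on the terminals weighted by shortest-path distances, take its
#' minimum spanning tree, expand each closure edge back into an actual
#' shortest path, and prune non-terminal leaves from the resulting
#' subgraph's spanning tree. With unit edge costs the tree cost is its
#' edge count; the approximation is within `2 (1 - 1/t)` of the optimum
#' for `t` terminals.
#'
#' @param network A connected `gene_network`.
#' @param terminals Character vector of node ids to span (all must be in
#'   the network).
#' @return An object of class `steiner_result`: list with `tree` (igraph),
#'   `terminals`, `cost` (edge count) and `nodes`.
#' @export
steiner_tree <- function(network, terminals) {
  stopifnot(inherits(network, "gene_network"))
  g <- network$graph
  terminals <- unique(as.character(terminals))
  missing <- setdiff(terminals, igraph::V(g)$name)
  if (length(missing) > 0) {
    abort(paste0("Terminal(s) not in network: ",
                 paste(missing, collapse = ", ")))
  }
  if (length(terminals) == 0) abort("Need at least one terminal.")
  if (igraph::components(g)$no > 1) {
    abort("Network must be connected; run clean_network() first.")
  }
  if (length(terminals) == 1) {
    tree <- igraph::induced_subgraph(g, terminals)
    return(structure(list(tree = tree, terminals = terminals, cost = 0,
                          nodes = terminals), class = "steiner_result"))
  }
  # metric closure on terminals
  dmat <- igraph::distances(g, v = terminals, to = terminals)
  idx <- which(upper.tri(dmat), arr.ind = TRUE)
  closure <- igraph::graph_from_data_frame(
    data.frame(from = terminals[idx[, 1]], to = terminals[idx[, 2]],
               weight = dmat[idx]),
    directed = FALSE)
  cmst <- igraph::mst(closure)
  cel <- igraph::as_edgelist(cmst)
  # expand closure edges into real shortest paths
  nodes <- character(0)
  edges <- character(0)
  for (r in seq_len(nrow(cel))) {
    sp <- igraph::shortest_paths(g, from = cel[r, 1], to = cel[r, 2],
                                 output = "vpath")$vpath[[1]]
    vn <- names(sp)
    nodes <- c(nodes, vn)
    if (length(vn) > 1) {
      edges <- c(edges, paste(pmin(vn[-length(vn)], vn[-1]),
                              pmax(vn[-length(vn)], vn[-1]), sep = "\r"))
    }
  }
  pairs <- do.call(rbind, strsplit(unique(edges), "\r", fixed = TRUE))
  sub <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2]), directed = FALSE)
  tree <- igraph::mst(sub)
  # prune non-terminal leaves until none remain
  repeat {
    deg <- igraph::degree(tree)
    drop <- names(deg)[deg <= 1 & !(names(deg) %in% terminals)]
    if (length(drop) == 0) break
    tree <- igraph::delete_vertices(tree, drop)
  }
  structure(list(tree = tree, terminals = terminals,
                 cost = igraph::ecount(tree),
                 nodes = sort(igraph::V(tree)$name)),
            class = "steiner_result")
}

#' @export
print.steiner_result <- function(x, ...) {
  cat("<steiner_result> ", length(x$terminals), " terminals spanned by ",
      length(x$nodes), " nodes / ", x$cost, " edges\n", sep = "")
  invisible(x)
}

#' Steiner tree edges as a tibble
#' @param x A `steiner_result`.
#' @param ... Unused.
#' @return Tibble (node_a, node_b), canonically ordered.
#' @exportS3Method generics::tidy
#' @export
tidy.steiner_result <- function(x, ...) {
  if (x$cost == 0) return(tibble(node_a = character(0), node_b = character(0)))
  el <- igraph::as_edgelist(x$tree)
  tibble(node_a = pmin(el[, 1], el[, 2]), node_b = pmax(el[, 1], el[, 2])) |>
    dplyr::arrange(.data$node_a, .data$node_b)
}
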