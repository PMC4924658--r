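write_edge_file <- function(edges, path, sif = TRUE) {
  if (sif) {
    writeLines(paste(edges$node_a, "pp", edges$node_b, sep = "\t"), path)
  } else {
    writeLines(c("node_a\tnode_b",
                 paste(edges$node_a, edges$node_b, sep = "\t")), path)
  }
  path
}

test_that("interaction loading unions files, dedups and drops self-loops", {
  tmp <- withr::local_tempdir()
  f1 <- write_edge_file(data.frame(node_a = "A", node_b = "B"),
                        file.path(tmp, "db1.sif"))
  f2 <- write_edge_file(data.frame(node_a = c("B", "C"), node_b = c("A", "C")),
                        file.path(tmp, "db2.tsv"), sif = FALSE)
  set <- load_interactions(c(f1, f2))
  ab <- set[set$node_a == "A" & set$node_b == "B", ]
  expect_equal(nrow(ab), 1)
  expect_identical(ab$source, "db1.sif;db2.tsv")
  expect_false(any(set$node_a == set$node_b))
  expect_equal(attr(set, "n_self_loops_dropped"), 1)

  bad <- file.path(tmp, "bad.sif")
  writeLines(c("A\tpp\tB", "oops"), bad)
  expect_error(load_interactions(bad), "line 2")
})

test_that("loading a partitioned edge table equals the single-file load", {
  tmp <- withr::local_tempdir()
  sim <- simulate_ppi(120, 3, seed = 19)
  edges <- sim$edges[, c("node_a", "node_b")]
  whole <- write_edge_file(edges, file.path(tmp, "all.sif"))
  thirds <- split(seq_len(nrow(edges)), rep(1:3, length.out = nrow(edges)))
  parts <- vapply(1:3, function(i) {
    write_edge_file(edges[thirds[[i]], ], file.path(tmp, paste0("p", i, ".sif")))
  }, character(1))
  a <- load_interactions(whole)
  b <- load_interactions(parts)
  expect_identical(a[, c("node_a", "node_b")], b[, c("node_a", "node_b")])
})

test_that("seed expansion matches a brute-force adjacency union", {
  star <- as_interaction_set(
    data.frame(node_a = "H", node_b = c("a", "b", "c")))
  net <- build_seed_network(star, "H", order = 1)
  expect_equal(igraph::vcount(net$graph), 4)
  expect_equal(igraph::ecount(net$graph), 3)
  expect_identical(igraph::V(net$graph)$role[igraph::V(net$graph)$name == "H"],
                   "root")

  net2 <- build_seed_network(star, c("H", "ZZZ"), order = 1)
  expect_identical(net2$report$missing_seeds, "ZZZ")
  expect_error(build_seed_network(star, "ZZZ"), "No seed")

  sim <- simulate_ppi(2000, 17, seed = 23)
  seeds <- sim$truth$hub_seeds
  net3 <- build_seed_network(sim$edges, seeds, order = 1)
  expected <- sort(unique(c(
    seeds,
    sim$edges$node_b[sim$edges$node_a %in% seeds],
    sim$edges$node_a[sim$edges$node_b %in% seeds])))
  expect_setequal(igraph::V(net3$graph)$name, expected)
})

test_that("cleaning keeps the largest component with a deterministic tie-break", {
  two_comp <- as_interaction_set(data.frame(
    node_a = c("a", "a", "a", "a", "x", "x"),
    node_b = c("b", "c", "d", "e", "y", "z")))
  net <- build_seed_network(two_comp, c("a", "x"), order = 1)
  cleaned <- clean_network(net)
  expect_equal(igraph::vcount(cleaned$graph), 5)

  tie <- as_interaction_set(data.frame(node_a = c("m", "b"),
                                       node_b = c("n", "c")))
  tied_net <- build_seed_network(tie, c("m", "b"), order = 1)
  kept <- clean_network(tied_net)
  expect_setequal(igraph::V(kept$graph)$name, c("b", "c"))

  # idempotence and connectivity by BFS oracle
  sim <- simulate_ppi(300, 5, seed = 29)
  net2 <- clean_network(build_seed_network(sim$edges, sim$truth$hub_seeds))
  again <- clean_network(net2)
  expect_identical(sort(igraph::V(net2$graph)$name),
                   sort(igraph::V(again$graph)$name))
  el <- igraph::as_edgelist(net2$graph)
  nodes <- igraph::V(net2$graph)$name
  seen <- nodes[1]
  frontier <- seen
  while (length(frontier) > 0) {
    nxt <- unique(c(el[el[, 1] %in% frontier, 2], el[el[, 2] %in% frontier, 1]))
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, frontier)
  }
  expect_setequal(seen, nodes)
})

test_that("topology matches brute-force neighbor-pair enumeration", {
  # non-interconnected hub: the formula's zero-CC case
  hub <- as_interaction_set(data.frame(
    node_a = "HUB", node_b = sprintf("i%03d", 1:843)))
  topo <- node_topology(build_seed_network(hub, "HUB"))
  h <- topo[topo$node == "HUB", ]
  expect_equal(h$k_n, 843)
  expect_equal(h$cc, 0)

  tri <- as_interaction_set(data.frame(node_a = c("a", "b", "c"),
                                       node_b = c("b", "c", "a")))
  topo_tri <- node_topology(build_seed_network(tri, "a"))
  expect_true(all(topo_tri$k_n == 2 & topo_tri$e_n == 1 & topo_tri$cc == 1))

  set.seed(31)
  n <- 200
  pairs <- t(combn(sprintf("v%03d", 1:n), 2))
  keep <- runif(nrow(pairs)) < 0.03
  edges <- data.frame(node_a = pairs[keep, 1], node_b = pairs[keep, 2])
  # seed with every node so the expanded network is the whole graph
  net <- build_seed_network(as_interaction_set(edges),
                            unique(c(edges$node_a, edges$node_b)))
  got <- node_topology(net)
  want <- oracle_topology(edges)
  want <- want[want$node %in% got$node, ]
  expect_equal(got$k_n, want$k_n, tolerance = 1e-12)
  expect_equal(got$e_n, want$e_n, tolerance = 1e-12)
  expect_equal(got$cc, want$cc, tolerance = 1e-12)
  expect_true(all(got$cc >= 0 & got$cc <= 1))

  # cross-check against igraph's local transitivity where defined
  tr <- igraph::transitivity(net$graph, type = "local", isolates = "zero")
  names(tr) <- igraph::V(net$graph)$name
  expect_equal(got$cc, unname(tr[got$node]), tolerance = 1e-12)
})

test_that("root ranking orders by degree, then CC, then id", {
  edges <- data.frame(
    node_a = c(rep("A", 10), rep("B", 3), "b1", rep("C", 3), "c1", "c2"),
    node_b = c(sprintf("a%02d", 1:10), sprintf("b%d", 1:3), "b2",
               sprintf("c%d", 1:3), "c2", "c3"))
  net <- build_seed_network(as_interaction_set(edges), c("A", "B", "C"))
  ranked <- rank_roots(net)
  expect_identical(ranked$node, c("A", "B", "C"))  # B: CC 1/3 < C: CC 1

  ranked2 <- rank_roots(net, roots = c("A", "B", "C", "GHOST"))
  expect_identical(attr(ranked2, "missing_roots"), "GHOST")

  sim <- simulate_ppi(500, 17, seed = 37)
  net2 <- clean_network(build_seed_network(sim$edges, sim$truth$hub_seeds))
  deg <- igraph::degree(net2$graph)
  top_planted <- names(which.max(deg[sim$truth$hub_seeds]))
  ranked3 <- rank_roots(net2)
  expect_equal(unname(deg[ranked3$node[1]]), max(deg[sim$truth$hub_seeds]))
})

test_that("signature-to-atlas matching equals brute-force recomputation", {
  sim <- simulate_ppi(400, 5, seed = 41)
  sig <- sim$truth$hub_seeds
  net <- match_signatures_to_atlas(sig, sim$edges)
  manual <- clean_network(build_seed_network(sim$edges, sig, order = 1))
  expect_setequal(igraph::V(net$graph)$name, igraph::V(manual$graph)$name)
  expect_error(match_signatures_to_atlas(c("NOPE1", "NOPE2"), sim$edges),
               class = "consignet_empty_network_error")

  tiny <- as_interaction_set(data.frame(node_a = c("S", "S"),
                                        node_b = c("p1", "p2")))
  net2 <- match_signatures_to_atlas("S", tiny)
  expect_equal(igraph::vcount(net2$graph), 3)
})

test_that("CC bounds hold across many random graphs", {
  for (s in 1:25) {
    sim <- simulate_ppi(60, 2, attachment = 2, seed = s)
    topo <- node_topology(build_seed_network(sim$edges, sim$truth$hub_seeds,
                                             order = 2))
    expect_true(all(topo$cc >= 0 & topo$cc <= 1))
    expect_true(all(topo$e_n <= topo$k_n * (topo$k_n - 1) / 2))
  }
})
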