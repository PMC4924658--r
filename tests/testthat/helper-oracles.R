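# Independent oracles used across the suite. Each recomputes a quantity by
# the most direct route available (enumeration, exact arithmetic, literal
# formula transcription) so it shares no code with the implementation.

# Exact right-tail hypergeometric probability via prime factorisation.
# Every binomial coefficient is represented as an integer exponent vector
# over the primes <= N (Legendre's formula), so each term's ratio is an
# exact rational; only the final product of prime powers rounds.
oracle_hyper_right <- function(x, n, K, N) {
  primes <- function(m) {
    if (m < 2) return(integer(0))
    sieve <- rep(TRUE, m)
    sieve[1] <- FALSE
    for (i in seq_len(floor(sqrt(m)))) {
      if (i >= 2 && sieve[i]) sieve[seq(i * i, m, by = i)] <- FALSE
    }
    which(sieve)
  }
  ps <- primes(max(N, 2))
  fact_exp <- function(m) {
    vapply(ps, function(p) {
      e <- 0
      pk <- p
      while (pk <= m) {
        e <- e + m %/% pk
        pk <- pk * p
      }
      e
    }, numeric(1))
  }
  choose_exp <- function(a, b) fact_exp(a) - fact_exp(b) - fact_exp(a - b)
  denom <- choose_exp(N, n)
  upper <- min(n, K)
  if (x > upper) return(0)
  total <- 0
  for (i in x:upper) {
    if (n - i > N - K) next
    e <- choose_exp(K, i) + choose_exp(N - K, n - i) - denom
    total <- total + prod(ps^e)
  }
  total
}

# Brute-force per-node degree / neighbor-edge count / clustering coefficient
# from a canonical edge data frame (no igraph).
oracle_topology <- function(edges, nodes = NULL) {
  pairs <- unique(data.frame(a = pmin(edges$node_a, edges$node_b),
                             b = pmax(edges$node_a, edges$node_b)))
  pairs <- pairs[pairs$a != pairs$b, ]
  nodes <- sort(unique(c(nodes, pairs$a, pairs$b)))
  key <- paste(pairs$a, pairs$b)
  adjacent <- function(u, v) paste(min(u, v), max(u, v)) %in% key
  res <- lapply(nodes, function(v) {
    nb <- sort(unique(c(pairs$b[pairs$a == v], pairs$a[pairs$b == v])))
    k <- length(nb)
    e <- 0
    if (k >= 2) {
      cmb <- combn(nb, 2)
      e <- sum(vapply(seq_len(ncol(cmb)),
                      function(j) adjacent(cmb[1, j], cmb[2, j]), logical(1)))
    }
    data.frame(node = v, k_n = k, e_n = e,
               cc = if (k >= 2) 2 * e / (k * (k - 1)) else 0)
  })
  do.call(rbind, res)
}

# Exhaustive Steiner optimum on a small graph: minimum |S| - 1 over node
# supersets S of the terminals whose induced subgraph is connected.
oracle_steiner_optimum <- function(edges, terminals) {
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  others <- setdiff(nodes, terminals)
  key <- paste(pmin(edges$node_a, edges$node_b),
               pmax(edges$node_a, edges$node_b))
  connected <- function(S) {
    seen <- S[1]
    frontier <- S[1]
    while (length(frontier) > 0) {
      nxt <- unique(unlist(lapply(frontier, function(v) {
        S[paste(pmin(v, S), pmax(v, S)) %in% key]
      })))
      frontier <- setdiff(nxt, seen)
      seen <- union(seen, frontier)
    }
    length(seen) == length(S)
  }
  best <- Inf
  for (sz in 0:length(others)) {
    if (length(terminals) + sz - 1 >= best) break
    subsets <- if (sz == 0) list(character(0)) else
      asplit(combn(others, sz), 2)
    for (extra in subsets) {
      S <- c(terminals, extra)
      if (connected(S)) {
        best <- min(best, length(S) - 1)
        break
      }
    }
  }
  best
}

# Literal transcription of the SAM statistic for one assignment.
oracle_sam_d <- function(mat, groups, s0) {
  vapply(seq_len(nrow(mat)), function(g) {
    x1 <- mat[g, groups == "control"]
    x2 <- mat[g, groups == "case"]
    n1 <- length(x1)
    n2 <- length(x2)
    s <- sqrt(((1 / n1 + 1 / n2) / (n1 + n2 - 2)) *
                (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)))
    (mean(x2) - mean(x1)) / (s + s0)
  }, numeric(1))
}

# Kaplan-Meier product-limit by direct risk-set recomputation.
oracle_km <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Two-group log-rank chi-square by per-event-time O/E/V enumeration.
oracle_logrank <- function(ta, ea, tb, eb) {
  ts <- sort(unique(c(ta[ea == 1], tb[eb == 1])))
  O <- E <- V <- 0
  for (t in ts) {
    n1 <- sum(ta >= t)
    n2 <- sum(tb >= t)
    d1 <- sum(ta == t & ea == 1)
    d2 <- sum(tb == t & eb == 1)
    n <- n1 + n2
    d <- d1 + d2
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Small multi-study cohort for unit tests (kept tiny for speed).
make_test_cohort <- function(seed = 1L, n_genes = 300, ...) {
  simulate_multistudy_expression(
    simulation_config(n_genes = n_genes, seed = seed, ...))
}
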