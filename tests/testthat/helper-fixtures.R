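# Fixtures and independent oracles shared across test files. Everything is
# built in code; no external data.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a bridge_network straight from a directed edge table
# (from, to, distance[, kind]).
make_network <- function(edges, nodes = NULL) {
  if (is.null(edges$kind)) edges$kind <- rep("PPI", nrow(edges))
  if (is.null(edges$distance)) edges$distance <- rep(1, nrow(edges))
  g <- if (is.null(nodes))
    igraph::graph_from_data_frame(edges, directed = TRUE)
  else
    igraph::graph_from_data_frame(edges, directed = TRUE,
                                  vertices = data.frame(name = nodes))
  bridgenet:::new_bridge_network(g)
}

# Unit-distance chain S -> A -> T1 (directed).
toy_chain <- function() {
  make_network(data.frame(from = c("S", "A"), to = c("A", "T1")))
}

# Random weighted digraph on n nodes; edge prob p, weights U[0, 1].
rand_digraph <- function(n, p = 0.35, seed = 1) {
  withr::with_seed(seed, {
    nodes <- sprintf("N%02d", seq_len(n))
    pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    pairs <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
    pairs$distance <- runif(nrow(pairs))
    make_network(pairs, nodes = nodes)
  })
}

# Exhaustive minimum simple-path distance between two nodes, by DFS on the
# raw edge table. Test-local oracle, independent of the package internals.
oracle_min_dist <- function(net, from, to) {
  ed <- igraph::as_data_frame(net$graph, what = "edges")
  if (from == to) return(0)
  best <- Inf
  recurse <- function(v, acc, seen) {
    if (v == to) { best <<- min(best, acc); return() }
    out <- ed[ed$from == v & !(ed$to %in% seen), , drop = FALSE]
    for (r in seq_len(nrow(out)))
      recurse(out$to[r], acc + out$distance[r], c(seen, out$to[r]))
  }
  recurse(from, 0, from)
  best
}

# All nodes i with a directed path from some sensor to i and from i to some
# enzyme, by plain DFS on the raw edge table (independent of igraph).
oracle_walk_nodes <- function(net, sensors, enzymes) {
  ed <- igraph::as_data_frame(net$graph, what = "edges")
  nodes <- igraph::V(net$graph)$name
  reach <- function(starts, forward = TRUE) {
    seen <- intersect(starts, nodes)
    repeat {
      nxt <- if (forward) ed$to[ed$from %in% seen] else ed$from[ed$to %in% seen]
      nxt <- setdiff(nxt, seen)
      if (!length(nxt)) return(seen)
      seen <- c(seen, nxt)
    }
  }
  intersect(reach(sensors, TRUE), reach(enzymes, FALSE))
}

# Small expression_matrix fixture with named classes.
toy_expr <- function(values, classes = NULL) {
  expression_matrix(values, sample_class = classes)
}
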