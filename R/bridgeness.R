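# Bridgeness scoring: shortest-path distances between sensors and enzymes,
# the per-node bridgeness sum, ranking, a brute-force oracle for small
# graphs, and classical centralities for comparison.

.edge_weights <- function(g) {
  w <- igraph::edge_attr(g, "distance")
  if (is.null(w)) return(NULL)
  if (any(w < 0)) stop("negative edge distance", call. = FALSE)
  w
}

.check_st <- function(network, S, T_) {
  S <- norm_symbols(S); T_ <- norm_symbols(T_)
  nodes <- network_nodes(network)
  S <- intersect(S, nodes); T_ <- intersect(T_, nodes)
  if (!length(S)) stop("no sensor present in network", call. = FALSE)
  if (!length(T_)) stop("no enzyme present in network", call. = FALSE)
  list(S = S, T = T_)
}

#' Shortest-path distances between sensors and enzymes
#'
#' Computes, over the directed graph weighted by edge distances, the
#' single-source distance map from every sensor and the distance map into
#' every enzyme (i.e. on the edge-reversed graph). Unreachable pairs are
#' `Inf`.
#'
#' @param network A `bridge_network` with non-negative edge distances.
#' @param S,T Sensor and enzyme gene sets.
#' @return A list with `from_sensor` (|S| x n matrix `d(s, .)`), `to_enzyme`
#'   (n x |T| matrix `d(., t)`) and `sensor_enzyme` (|S| x |T| matrix
#'   `d(s, t)`).
#' @export
sensor_enzyme_distances <- function(network, S, T) {
  stopifnot(inherits(network, "bridge_network"))
  st <- .check_st(network, S, T)
  g <- network$graph
  w <- .edge_weights(g)
  dS <- igraph::distances(g, v = st$S, mode = "out", weights = w)
  dT <- t(igraph::distances(g, v = st$T, mode = "in", weights = w))
  list(from_sensor = dS,
       to_enzyme = dT,
       sensor_enzyme = dS[, st$T, drop = FALSE],
       S = st$S, T = st$T)
}

# Addend of the bridgeness sum for one (s, t, i) triple, given the pair's
# shortest-path distance dst and the via-i distance dvia = d(s,i) + d(i,t).
# Kept in one place so the functional form is a one-line change.
.bridgeness_addend <- function(dst, dvia) {
  a <- ifelse(is.infinite(dst) | is.infinite(dvia), 0,
              ifelse(dst == 0 & dvia == 0, 1, dst / dvia))
  # dst <= dvia by shortest-path optimality; guard rounding
  pmin(a, 1)
}

#' Bridgeness score of an intermediate node
#'
#' The bridgeness of gene `i` over sensors `S` and enzymes `T` is
#' `B_i = sum over (s, t) of d(s, t) / d_i(s, t)` where `d(s, t)` is the
#' shortest-path distance from `s` to `t` and `d_i(s, t) = d(s, i) + d(i, t)`
#' is the shortest path via `i`. Each addend lies in `[0, 1]`: it is 1 when
#' `i` is on a shortest s-t path and tends to 0 as `i` moves far from it.
#' Pairs with `d(s, t)` or `d_i(s, t)` infinite contribute 0; the degenerate
#' zero-distance case (`d(s, t) = d_i(s, t) = 0`, perfectly correlated
#' chains) contributes 1 by convention.
#'
#' @param network A `bridge_network`.
#' @param S,T Sensor and enzyme gene sets.
#' @param i An intermediate node (not in `S` or `T`).
#' @param dmaps Optional precomputed [sensor_enzyme_distances()] result.
#' @return The score, in `[0, |S|*|T|]`.
#' @export
bridgeness <- function(network, S, T, i, dmaps = NULL) {
  i <- norm_symbols(i)
  st <- .check_st(network, S, T)
  if (i %in% c(st$S, st$T))
    stop("bridgeness is defined for intermediate nodes only", call. = FALSE)
  if (!(i %in% network_nodes(network)))
    stop(sprintf("node %s not in network", i), call. = FALSE)
  dmaps <- dmaps %||% sensor_enzyme_distances(network, st$S, st$T)
  dvia <- outer(dmaps$from_sensor[, i], dmaps$to_enzyme[i, ], `+`)
  sum(.bridgeness_addend(dmaps$sensor_enzyme, dvia))
}

# Scores and contributing-pair counts for a set of intermediates at once.
.bridgeness_table_core <- function(network, S, T_, intermediates) {
  dmaps <- sensor_enzyme_distances(network, S, T_)
  score <- numeric(length(intermediates))
  npair <- integer(length(intermediates))
  for (j in seq_along(intermediates)) {
    i <- intermediates[j]
    dvia <- outer(dmaps$from_sensor[, i], dmaps$to_enzyme[i, ], `+`)
    a <- .bridgeness_addend(dmaps$sensor_enzyme, dvia)
    score[j] <- sum(a)
    npair[j] <- sum(a > 0)
  }
  data.frame(gene = intermediates, score = score, n_pairs = npair,
             stringsAsFactors = FALSE)
}

#' Rank candidate bridge proteins by bridgeness
#'
#' Scores every intermediate node and returns the top `k`, sorted by
#' descending score with ties broken by ascending gene symbol.
#'
#' @param network A `bridge_network` with roles assigned, or supply `S`/`T`.
#' @param S,T Sensor and enzyme sets; default to the network's role
#'   annotation.
#' @param k Number of top genes returned; if it exceeds the number of
#'   intermediates, all are returned with a warning.
#' @return A `bridgeness_table` data.frame: `gene`, `score`, `rank`,
#'   `n_pairs` (number of sensor-enzyme pairs with a positive addend).
#' @export
rank_bridges <- function(network, S = NULL, T = NULL, k = 50) {
  stopifnot(inherits(network, "bridge_network"), k >= 1)
  S <- S %||% network_nodes(network, "sensor")
  T <- T %||% network_nodes(network, "enzyme")
  st <- .check_st(network, S, T)
  inter <- setdiff(network_nodes(network), c(st$S, st$T))
  if (!length(inter)) stop("network has no intermediate nodes", call. = FALSE)
  tab <- .bridgeness_table_core(network, st$S, st$T, inter)
  tab <- tab[order(-tab$score, tab$gene), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  if (k > nrow(tab)) {
    warning(sprintf("k = %d exceeds %d intermediates; returning all",
                    k, nrow(tab)), call. = FALSE)
    k <- nrow(tab)
  }
  out <- tab[seq_len(k), c("gene", "score", "rank", "n_pairs")]
  class(out) <- c("bridgeness_table", "data.frame")
  out
}

# ---- brute-force oracle ---------------------------------------------------

# Minimum total distance over all simple paths from `from` to `to`, by
# exhaustive depth-first enumeration on the raw edge list. Independent of
# igraph's shortest-path machinery by design.
.bf_min_dist <- function(adj, w, from, to) {
  if (from == to) return(0)
  best <- Inf
  visited <- logical(length(adj))
  recurse <- function(v, acc) {
    if (acc >= best) return()
    if (v == to) { best <<- acc; return() }
    visited[v] <<- TRUE
    nb <- adj[[v]]
    for (k in seq_along(nb)) {
      u <- nb[k]
      if (!visited[u]) recurse(u, acc + w[[v]][k])
    }
    visited[v] <<- FALSE
  }
  recurse(from, 0)
  best
}

#' Brute-force bridgeness (testing oracle)
#'
#' Identical contract to [bridgeness()], but every distance is obtained by
#' exhaustive enumeration of simple paths. Refuses networks with more than
#' 12 nodes.
#'
#' @inheritParams bridgeness
#' @return The score.
#' @export
bridgeness_bruteforce <- function(network, S, T, i) {
  stopifnot(inherits(network, "bridge_network"))
  g <- network$graph
  n <- igraph::vcount(g)
  if (n > 12) stop("brute-force oracle limited to <= 12 nodes", call. = FALSE)
  i <- norm_symbols(i)
  S <- intersect(norm_symbols(S), network_nodes(network))
  T_ <- intersect(norm_symbols(T), network_nodes(network))
  if (!length(S) || !length(T_)) return(0)
  if (i %in% c(S, T_))
    stop("bridgeness is defined for intermediate nodes only", call. = FALSE)
  nm <- igraph::V(g)$name
  ed <- igraph::as_data_frame(g, what = "edges")
  if (nrow(ed) && any(ed$distance < 0)) stop("negative edge distance", call. = FALSE)
  adj <- rep(list(integer()), n)
  w <- rep(list(numeric()), n)
  for (r in seq_len(nrow(ed))) {
    a <- match(ed$from[r], nm); b <- match(ed$to[r], nm)
    adj[[a]] <- c(adj[[a]], b)
    w[[a]] <- c(w[[a]], ed$distance[r])
  }
  ii <- match(i, nm)
  total <- 0
  for (s in match(S, nm)) for (t in match(T_, nm)) {
    dst <- .bf_min_dist(adj, w, s, t)
    dvia <- .bf_min_dist(adj, w, s, ii) + .bf_min_dist(adj, w, ii, t)
    total <- total + .bridgeness_addend(dst, dvia)
  }
  total
}

#' Classical centralities for comparison
#'
#' Degree, harmonic closeness and betweenness on the directed weighted
#' graph. Closeness uses the harmonic form (mean of inverse distances) so
#' unreachable pairs contribute 0 rather than breaking the average.
#' Zero-distance edges are raised to 1e-12 for the betweenness computation,
#' which requires strictly positive weights.
#'
#' @param network A `bridge_network`.
#' @param nodes Nodes to report (default all).
#' @return data.frame: `gene`, `degree`, `closeness`, `betweenness`.
#' @export
standard_centralities <- function(network, nodes = NULL) {
  stopifnot(inherits(network, "bridge_network"))
  g <- network$graph
  nodes <- norm_symbols(nodes %||% network_nodes(network))
  w <- .edge_weights(g)
  wpos <- if (is.null(w)) NULL else pmax(w, 1e-12)
  deg <- igraph::degree(g, mode = "all")
  clo <- igraph::harmonic_centrality(g, mode = "out", weights = w,
                                     normalized = FALSE)
  btw <- igraph::betweenness(g, directed = TRUE, weights = wpos)
  data.frame(gene = nodes,
             degree = unname(deg[nodes]),
             closeness = unname(clo[nodes]),
             betweenness = unname(btw[nodes]),
             stringsAsFactors = FALSE)
}
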