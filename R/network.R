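# Construction of the constrained, weighted, directed reference ("bridge")
# network: interaction integration, co-expression edge distances, the
# tissue-expression node filter, and extraction of the sensor/enzyme/
# intermediate subnetwork.

new_bridge_network <- function(graph, provenance = list()) {
  if (is.null(igraph::vertex_attr(graph, "role")))
    igraph::V(graph)$role <- "intermediate"
  if (igraph::ecount(graph) && is.null(igraph::edge_attr(graph, "kind")))
    igraph::E(graph)$kind <- "PPI"
  if (igraph::ecount(graph) && is.null(igraph::edge_attr(graph, "distance")))
    igraph::E(graph)$distance <- 1
  structure(list(graph = graph, provenance = provenance),
            class = "bridge_network")
}

#' @export
print.bridge_network <- function(x, ...) {
  g <- x$graph
  roles <- table(factor(igraph::V(g)$role,
                        levels = c("sensor", "enzyme", "intermediate")))
  cat(sprintf("bridge_network: %d nodes (%d sensors, %d enzymes, %d intermediates), %d directed edges\n",
              igraph::vcount(g), roles[["sensor"]], roles[["enzyme"]],
              roles[["intermediate"]], igraph::ecount(g)))
  invisible(x)
}

#' Node names of a bridge network
#' @param network A `bridge_network`.
#' @param role Optional role filter (`"sensor"`, `"enzyme"`, `"intermediate"`).
#' @return Character vector of gene symbols.
#' @export
network_nodes <- function(network, role = NULL) {
  stopifnot(inherits(network, "bridge_network"))
  nm <- igraph::V(network$graph)$name
  if (is.null(role)) return(nm)
  nm[igraph::V(network$graph)$role %in% role]
}

#' Integrate PPI and PDI records into a directed network
#'
#' Every protein-protein interaction contributes two antiparallel directed
#' edges; every protein-DNA interaction contributes a single directed edge
#' from the transcription factor to its target. Self-loops are dropped and
#' duplicate directed edges are merged, labelling a merged edge `PDI` when
#' both kinds support it (kind priority PDI > PPI). All edge distances are
#' initialized to 1 (maximal) until [assign_edge_distances()] runs.
#'
#' @param ppi,pdi data.frames from [read_interaction_table()] (either may be
#'   empty).
#' @return A `bridge_network` with all node roles set to `"intermediate"`.
#' @export
integrate_interactions <- function(ppi = NULL, pdi = NULL) {
  empty <- data.frame(source = character(), target = character(),
                      stringsAsFactors = FALSE)
  ppi <- ppi %||% empty
  pdi <- pdi %||% empty
  ed <- rbind(
    if (nrow(ppi)) data.frame(from = c(ppi$source, ppi$target),
                              to = c(ppi$target, ppi$source),
                              kind = "PPI", stringsAsFactors = FALSE),
    if (nrow(pdi)) data.frame(from = pdi$source, to = pdi$target,
                              kind = "PDI", stringsAsFactors = FALSE))
  if (is.null(ed))
    ed <- data.frame(from = character(), to = character(), kind = character())
  ed <- ed[ed$from != ed$to, , drop = FALSE]
  if (nrow(ed)) {
    # merge duplicate directed edges, PDI label winning over PPI
    key <- paste(ed$from, ed$to, sep = "\r")
    ord <- order(key, ed$kind != "PDI")  # PDI rows first within a key
    ed <- ed[ord, , drop = FALSE]
    ed <- ed[!duplicated(paste(ed$from, ed$to, sep = "\r")), , drop = FALSE]
  }
  ed$distance <- rep(1, nrow(ed))
  g <- igraph::graph_from_data_frame(ed, directed = TRUE)
  new_bridge_network(g, provenance = list(
    n_ppi_records = nrow(ppi), n_pdi_records = nrow(pdi)))
}

#' Co-expression distance
#'
#' Maps a correlation coefficient to the edge distance `d = 1 - r^2`, so
#' strongly co-expressed gene pairs (of either sign) are close.
#'
#' @param r Pearson correlation coefficient(s) in `[-1, 1]`.
#' @return `1 - r^2`, in `[0, 1]`.
#' @export
coexpression_distance <- function(r) {
  if (any(!is.na(r) & abs(r) > 1 + 1e-12))
    stop("correlation outside [-1, 1]", call. = FALSE)
  r <- pmin(pmax(r, -1), 1)
  1 - r^2
}

#' Assign co-expression distances to every edge
#'
#' For each directed edge the distance is `1 - r^2` with `r` the Pearson
#' correlation of the endpoint genes' expression across samples. Edges with
#' an endpoint missing from the matrix, or with undefined correlation (zero
#' variance), get the maximal distance 1 (messaged).
#'
#' @param network A `bridge_network`.
#' @param expr An [expression_matrix()] used purely for co-expression.
#' @return The network with updated `distance` edge attribute; provenance
#'   records the number of fallback edges.
#' @export
assign_edge_distances <- function(network, expr) {
  stopifnot(inherits(network, "bridge_network"),
            inherits(expr, "expression_matrix"))
  g <- network$graph
  if (!igraph::ecount(g)) return(network)
  ed <- igraph::as_data_frame(g, what = "edges")
  have <- rownames(expr$values)
  d <- numeric(nrow(ed))
  fallback <- 0L
  for (i in seq_len(nrow(ed))) {
    a <- ed$from[i]; b <- ed$to[i]
    if (!(a %in% have) || !(b %in% have)) {
      d[i] <- 1; fallback <- fallback + 1L; next
    }
    x <- expr$values[a, ]; y <- expr$values[b, ]
    ok <- !is.na(x) & !is.na(y)
    r <- if (sum(ok) >= 2 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
      stats::cor(x[ok], y[ok]) else NA_real_
    if (is.na(r)) {
      d[i] <- 1; fallback <- fallback + 1L
    } else d[i] <- coexpression_distance(r)
  }
  if (fallback)
    message(sprintf("%d edges with missing/degenerate expression set to d = 1",
                    fallback))
  if (fallback == nrow(ed))
    warning("no edge had measurable co-expression; all distances are 1",
            call. = FALSE)
  igraph::E(g)$distance <- d
  network$graph <- g
  network$provenance$coexpression_fallback_edges <- fallback
  network
}

#' Tissue panel for node filtering
#'
#' @param values Numeric matrix, genes x tissue samples.
#' @param target_samples Column ids of the target tissue (e.g. colon);
#'   must be a non-empty subset of `colnames(values)`.
#' @return An object of class `tissue_panel`.
#' @export
tissue_panel <- function(values, target_samples) {
  values <- as.matrix(values)
  if (!nrow(values) || !ncol(values)) stop("empty tissue panel", call. = FALSE)
  rownames(values) <- norm_symbols(rownames(values))
  target_samples <- as.character(target_samples)
  if (!length(target_samples) || !all(target_samples %in% colnames(values)))
    stop("target_samples must be a non-empty subset of panel columns",
         call. = FALSE)
  structure(list(values = values, target_samples = target_samples),
            class = "tissue_panel")
}

#' Filter network nodes by relative tissue expression
#'
#' For each gene in the panel the ratio of its mean expression in the target
#' tissue samples to its mean across all panel samples is computed; nodes
#' whose ratio falls below the `percentile_cutoff`-th percentile of the
#' ratio distribution (over genes present in both panel and network) are
#' removed. Sensors and enzymes are exempt, as are genes absent from the
#' panel (messaged).
#'
#' @param network A `bridge_network` (roles already assigned if sensors or
#'   enzymes should be protected).
#' @param panel A [tissue_panel()].
#' @param percentile_cutoff Percentile in `[0, 100]`; default 40.
#' @param exempt Extra gene symbols never removed; defaults to nodes whose
#'   role is not `"intermediate"`.
#' @return The filtered `bridge_network`.
#' @export
filter_by_tissue_expression <- function(network, panel, percentile_cutoff = 40,
                                        exempt = NULL) {
  stopifnot(inherits(network, "bridge_network"), inherits(panel, "tissue_panel"))
  if (percentile_cutoff < 0 || percentile_cutoff > 100)
    stop("percentile_cutoff must be in [0, 100]", call. = FALSE)
  nodes <- network_nodes(network)
  exempt <- unique(c(norm_symbols(exempt %||% character()),
                     nodes[igraph::V(network$graph)$role != "intermediate"]))
  tm <- rowMeans(panel$values[, panel$target_samples, drop = FALSE], na.rm = TRUE)
  am <- rowMeans(panel$values, na.rm = TRUE)
  ratio <- tm / am
  shared <- intersect(nodes, names(ratio))
  absent <- setdiff(nodes, names(ratio))
  if (length(absent))
    message(sprintf("%d network genes absent from tissue panel retained",
                    length(absent)))
  if (!length(shared)) return(network)
  thr <- stats::quantile(ratio[shared], probs = percentile_cutoff / 100,
                         names = FALSE, na.rm = TRUE)
  drop <- shared[!is.na(ratio[shared]) & ratio[shared] < thr]
  drop <- setdiff(drop, exempt)
  g <- igraph::delete_vertices(network$graph, drop)
  network$graph <- g
  network$provenance$tissue_filter <- list(
    percentile_cutoff = percentile_cutoff, removed = length(drop))
  network
}

#' Assign sensor/enzyme/intermediate roles
#'
#' A gene listed as both sensor and enzyme is assigned `enzyme` (messaged).
#'
#' @param network A `bridge_network`.
#' @param sensors,enzymes Character vectors of gene symbols.
#' @return The network with the `role` vertex attribute set.
#' @export
assign_node_roles <- function(network, sensors, enzymes) {
  stopifnot(inherits(network, "bridge_network"))
  sensors <- norm_symbols(sensors); enzymes <- norm_symbols(enzymes)
  both <- intersect(sensors, enzymes)
  if (length(both)) {
    message(sprintf("%d genes listed as both sensor and enzyme assigned enzyme",
                    length(both)))
    sensors <- setdiff(sensors, both)
  }
  g <- network$graph
  role <- rep("intermediate", igraph::vcount(g))
  nm <- igraph::V(g)$name
  role[nm %in% sensors] <- "sensor"
  role[nm %in% enzymes] <- "enzyme"
  igraph::V(g)$role <- role
  network$graph <- g
  network
}

#' Extract the reference (bridge) network
#'
#' Assigns roles and keeps a node iff it is a sensor or enzyme, or it lies
#' on some directed sensor-to-enzyme walk (reachable from a sensor and
#' reaching an enzyme along edge directions).
#'
#' @param network A `bridge_network`.
#' @param sensors,enzymes Gene symbol sets; members missing from the network
#'   trigger a warning, and an entirely absent set is an error.
#' @return The pruned `bridge_network` with roles assigned. Idempotent. With
#'   `sensors = enzymes =` all nodes it is the identity (the whole-network
#'   variant).
#' @export
extract_reference_network <- function(network, sensors, enzymes) {
  stopifnot(inherits(network, "bridge_network"))
  sensors <- norm_symbols(sensors); enzymes <- norm_symbols(enzymes)
  nodes <- network_nodes(network)
  miss <- setdiff(c(sensors, enzymes), nodes)
  if (length(miss))
    warning(sprintf("%d sensor/enzyme genes not in network: %s",
                    length(miss), paste(utils::head(miss, 5), collapse = ", ")),
            call. = FALSE)
  if (!length(intersect(sensors, nodes)))
    stop("no sensor present in the network", call. = FALSE)
  if (!length(intersect(enzymes, nodes)))
    stop("no enzyme present in the network", call. = FALSE)
  network <- assign_node_roles(network, sensors, enzymes)
  g <- network$graph
  nm <- igraph::V(g)$name
  # reachability along edge directions from/to the *given* sets (a gene
  # listed as both sensor and enzyme counts for both), ignoring weights
  s_idx <- which(nm %in% sensors)
  t_idx <- which(nm %in% enzymes)
  from_s <- igraph::distances(g, v = s_idx, mode = "out", weights = NA)
  to_t <- igraph::distances(g, v = t_idx, mode = "in", weights = NA)
  on_walk <- apply(is.finite(from_s), 2, any) & apply(is.finite(to_t), 2, any)
  keep <- on_walk | nm %in% c(sensors, enzymes)
  network$graph <- igraph::induced_subgraph(g, which(keep))
  network$provenance$sensors <- intersect(sensors, nodes)
  network$provenance$enzymes <- intersect(enzymes, nodes)
  network
}
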