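ppi_rec <- function(a, b) data.frame(source = a, target = b, kind = "PPI",
                                     directed = FALSE, stringsAsFactors = FALSE)
pdi_rec <- function(a, b) data.frame(source = a, target = b, kind = "PDI",
                                     directed = TRUE, stringsAsFactors = FALSE)

test_that("integration makes PPIs bidirectional, PDIs one-way, merges duplicates", {
  net <- integrate_interactions(ppi_rec("A", "B"), NULL)
  ed <- igraph::as_data_frame(net$graph, "edges")
  expect_setequal(paste(ed$from, ed$to), c("A B", "B A"))

  net <- integrate_interactions(NULL, pdi_rec("TF1", "G1"))
  ed <- igraph::as_data_frame(net$graph, "edges")
  expect_equal(paste(ed$from, ed$to), "TF1 G1")

  # PPI {A,B} + PDI A->B: A->B merged (labelled PDI) plus B->A
  net <- integrate_interactions(ppi_rec("A", "B"), pdi_rec("A", "B"))
  ed <- igraph::as_data_frame(net$graph, "edges")
  expect_equal(nrow(ed), 2L)
  expect_equal(ed$kind[ed$from == "A"], "PDI")
  expect_equal(ed$kind[ed$from == "B"], "PPI")

  # self-loops dropped; empty input tolerated
  net <- integrate_interactions(ppi_rec("A", "A"), NULL)
  expect_equal(igraph::ecount(net$graph), 0)
  expect_equal(igraph::vcount(integrate_interactions(NULL, NULL)$graph), 0)
})

test_that("co-expression distance is 1 - r^2, symmetric in sign", {
  expect_equal(coexpression_distance(1), 0)
  expect_equal(coexpression_distance(-1), 0)
  expect_equal(coexpression_distance(0.5), 0.75)
  expect_equal(coexpression_distance(c(0, -0.3)), c(1, 1 - 0.09))
  expect_error(coexpression_distance(1.2), "outside")
})

test_that("edge distances come from endpoint correlation with d = 1 fallback", {
  net <- make_network(data.frame(from = c("A", "A", "A"),
                                 to = c("B", "C", "ZZ")))
  vals <- rbind(A = c(1, 2, 3), B = c(2, 4, 6), C = c(1, 2, 4))
  colnames(vals) <- paste0("s", 1:3)
  expect_message(net2 <- assign_edge_distances(net, toy_expr(vals)),
                 "set to d = 1")
  ed <- igraph::as_data_frame(net2$graph, "edges")
  d <- setNames(ed$distance, ed$to)
  # identical (perfectly proportional) rows -> r = 1 -> d = 0
  expect_equal(unname(d["B"]), 0)
  # textbook sample-correlation hand computation for [1,2,3] vs [1,2,4]:
  # Sxy = 3, Sxx = 2, Syy = 14/3 -> r^2 = 9/(2*14/3) = 27/28, d = 1/28
  expect_equal(unname(d["C"]), 1 / 28, tolerance = 1e-12)
  # endpoint absent from the matrix -> maximal distance
  expect_equal(unname(d["ZZ"]), 1)
})

test_that("edge distances are invariant under sample permutation", {
  net <- make_network(data.frame(from = c("A", "B"), to = c("B", "C")))
  vals <- matrix(rnorm(15), 3, 5,
                 dimnames = list(c("A", "B", "C"), paste0("s", 1:5)))
  d1 <- igraph::as_data_frame(
    assign_edge_distances(net, toy_expr(vals))$graph, "edges")$distance
  perm <- vals[, c(4, 1, 5, 2, 3)]
  d2 <- igraph::as_data_frame(
    assign_edge_distances(net, toy_expr(perm))$graph, "edges")$distance
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("tissue filter removes low-ratio intermediates, exempts sensors/enzymes", {
  nodes <- sprintf("G%02d", 1:10)
  edges <- data.frame(from = nodes[1:9], to = nodes[2:10])
  panel_vals <- matrix(10, 10, 4, dimnames = list(nodes, paste0("t", 1:4)))
  # colonic mean / overall mean ratios 0.1, 0.2, ..., 1.0 by construction
  for (i in 1:10) {
    r <- i / 10
    overall <- 10
    colonic <- overall * r
    panel_vals[i, ] <- c(colonic, colonic,
                         (4 * overall - 2 * colonic) / 2,
                         (4 * overall - 2 * colonic) / 2)
  }
  panel <- tissue_panel(panel_vals, target_samples = c("t1", "t2"))

  net <- make_network(edges)
  # brute-force 40th percentile of the ten ratios (type-7 interpolation)
  ratios <- (1:10) / 10
  q40 <- sort(ratios)[5] * 0.6 + sort(ratios)[4] * 0.4  # 1 + 0.4*9 = 4.6
  expect_equal(unname(quantile(ratios, 0.4)), q40)
  filt <- filter_by_tissue_expression(net, panel, 40)
  expect_setequal(network_nodes(filt), nodes[ratios >= q40])

  # cutoff 0 leaves the network unchanged
  expect_setequal(network_nodes(filter_by_tissue_expression(net, panel, 0)),
                  nodes)

  # a sensor with the lowest ratio survives even at cutoff 100
  net2 <- assign_node_roles(make_network(edges), sensors = "G01",
                           enzymes = "G10")
  filt2 <- filter_by_tissue_expression(net2, panel, 100)
  expect_true(all(c("G01", "G10") %in% network_nodes(filt2)))

  expect_error(tissue_panel(matrix(nrow = 0, ncol = 0), "t1"), "empty")
})

test_that("tissue filtering is monotone in the cutoff", {
  net <- make_network(data.frame(from = sprintf("G%02d", 1:9),
                                 to = sprintf("G%02d", 2:10)))
  vals <- matrix(abs(rnorm(40, 10)), 10, 4,
                 dimnames = list(sprintf("G%02d", 1:10), paste0("t", 1:4)))
  panel <- tissue_panel(vals, c("t1", "t2"))
  prev <- network_nodes(net)
  for (cut in c(0, 20, 40, 60, 80, 100)) {
    now <- network_nodes(filter_by_tissue_expression(net, panel, cut))
    expect_true(all(now %in% prev), info = paste("cutoff", cut))
    prev <- now
  }
})

test_that("reference extraction keeps exactly the sensor-to-enzyme walk nodes", {
  # chain s -> a -> t plus isolated z
  net <- make_network(data.frame(from = c("S", "A"), to = c("A", "T1")),
                      nodes = c("S", "A", "T1", "Z"))
  ref <- extract_reference_network(net, "S", "T1")
  expect_setequal(network_nodes(ref), c("S", "A", "T1"))

  # b reachable from s but not reaching any enzyme -> dropped
  net2 <- make_network(data.frame(from = c("S", "A", "S"),
                                  to = c("A", "T1", "B")))
  expect_setequal(network_nodes(extract_reference_network(net2, "S", "T1")),
                  c("S", "A", "T1"))

  expect_error(extract_reference_network(net, "NOPE", "T1"), "no sensor")
  expect_error(extract_reference_network(net, "S", "NOPE"), "no enzyme")
})

test_that("extraction matches exhaustive walk enumeration on random digraphs", {
  for (seed in 1:10) {
    net <- rand_digraph(8, p = 0.25, seed = seed)
    nodes <- network_nodes(net)
    sensors <- nodes[1:2]
    enzymes <- nodes[7:8]
    expected <- union(oracle_walk_nodes(net, sensors, enzymes),
                      c(sensors, enzymes))
    got <- suppressWarnings(
      tryCatch(extract_reference_network(net, sensors, enzymes),
               error = function(e) NULL))
    if (is.null(got)) next
    expect_setequal(network_nodes(got), expected)
  }
})

test_that("extraction is idempotent and identity for the whole-network variant", {
  net <- rand_digraph(8, p = 0.3, seed = 42)
  nodes <- network_nodes(net)
  once <- extract_reference_network(net, nodes[1], nodes[8])
  twice <- extract_reference_network(once, nodes[1], nodes[8])
  expect_setequal(network_nodes(twice), network_nodes(once))
  expect_equal(igraph::ecount(twice$graph), igraph::ecount(once$graph))

  whole <- extract_reference_network(net, nodes, nodes)
  expect_setequal(network_nodes(whole), nodes)
  expect_equal(igraph::ecount(whole$graph), igraph::ecount(net$graph))
})
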