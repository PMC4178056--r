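# Synthetic input generators with known ground truth: a sensor-bridge-enzyme
# interactome with planted relays, block-correlated class-differential
# expression, and right-censored survival cohorts driven by a planted
# signature. Every generator is a pure function of its parameters and seed.

#' Simulate a sensor-bridge-enzyme interactome with planted relays
#'
#' Every sensor is connected to every planted bridge by a protein-DNA edge
#' and every bridge to every enzyme by a protein-protein edge, so sensors
#' reach enzymes exclusively through the bridge layer. Random decoy PPI
#' edges are then proposed among the non-bridge nodes (sensors, enzymes and
#' decoy intermediates) at probability `decoy_edge_prob` per pair and
#' accepted only if they do not open a sensor-to-enzyme path avoiding all
#' bridges (rejection by reachability), so the planted relays remain the
#' only conduits.
#'
#' @param n_nodes Total node count (sensors + enzymes + bridges + decoys).
#' @param n_sensors,n_enzymes,n_bridges Layer sizes; `n_bridges >= 1`.
#' @param decoy_edge_prob Per-pair probability of proposing a decoy edge.
#' @param seed Integer seed.
#' @return List with `ppi`, `pdi` (interaction record data.frames) and
#'   `truth` (planted gene sets, parameters, seed).
#' @export
simulate_interactome <- function(n_nodes = 38, n_sensors = 2, n_enzymes = 3,
                                 n_bridges = 3, decoy_edge_prob = 0.08,
                                 seed = 1L) {
  n_decoys <- n_nodes - n_sensors - n_enzymes - n_bridges
  if (n_bridges < 1 || n_sensors < 1 || n_enzymes < 1 || n_decoys < 0)
    stop("infeasible layer sizes", call. = FALSE)
  sensors <- sprintf("SEN%02d", seq_len(n_sensors))
  enzymes <- sprintf("ENZ%02d", seq_len(n_enzymes))
  bridges <- sprintf("BRG%02d", seq_len(n_bridges))
  decoys <- if (n_decoys) sprintf("DCY%02d", seq_len(n_decoys)) else character()
  pdi <- expand.grid(source = sensors, target = bridges,
                     stringsAsFactors = FALSE)
  ppi <- expand.grid(source = bridges, target = enzymes,
                     stringsAsFactors = FALSE)
  nb <- c(sensors, enzymes, decoys)  # non-bridge nodes
  with_rng_seed(seed, {
    pairs <- which(upper.tri(matrix(0, length(nb), length(nb))), arr.ind = TRUE)
    take <- stats::runif(nrow(pairs)) < decoy_edge_prob
    pairs <- pairs[take, , drop = FALSE]
    if (nrow(pairs)) pairs <- pairs[sample(nrow(pairs)), , drop = FALSE]
    # undirected adjacency among non-bridge nodes for the rejection check
    adj <- rep(list(integer()), length(nb))
    s_idx <- seq_len(n_sensors)
    e_idx <- n_sensors + seq_len(n_enzymes)
    reaches_enzyme <- function(adj, start) {
      seen <- logical(length(adj)); queue <- start; seen[start] <- TRUE
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        if (v %in% e_idx) return(TRUE)
        for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
      }
      FALSE
    }
    keep <- logical(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      adj2 <- adj
      adj2[[a]] <- c(adj2[[a]], b)
      adj2[[b]] <- c(adj2[[b]], a)
      if (any(vapply(s_idx, function(s) reaches_enzyme(adj2, s), logical(1))))
        next  # would open a bridge-free sensor-to-enzyme path
      adj <- adj2
      keep[r] <- TRUE
    }
    pairs <- pairs[keep, , drop = FALSE]
  })
  if (nrow(pairs))
    ppi <- rbind(ppi, data.frame(source = nb[pairs[, 1]],
                                 target = nb[pairs[, 2]],
                                 stringsAsFactors = FALSE))
  ppi$kind <- "PPI"; ppi$directed <- FALSE
  pdi$kind <- "PDI"; pdi$directed <- TRUE
  truth <- list(sensors = sensors, enzymes = enzymes, bridges = bridges,
                decoys = decoys,
                params = list(n_nodes = n_nodes, n_sensors = n_sensors,
                              n_enzymes = n_enzymes, n_bridges = n_bridges,
                              decoy_edge_prob = decoy_edge_prob),
                seed = seed)
  list(ppi = ppi, pdi = pdi, truth = truth)
}

#' Simulate class-labelled expression with differential and correlated genes
#'
#' Gaussian background (mean 0, sd 1); the declared differential genes are
#' shifted by `effect_size` in the tumor class; genes sharing a declared
#' correlation block are drawn with pairwise correlation `corr_block_rho`
#' via a shared latent factor.
#'
#' @param genes Gene universe (character).
#' @param n_per_class Named integer vector of samples per class, e.g.
#'   `c(normal = 20, tumor = 20)`.
#' @param diff_genes Subset of `genes` shifted in the `tumor` class.
#' @param effect_size Mean shift (|effect| < 10).
#' @param corr_blocks List of gene vectors; members of a block share
#'   pairwise correlation `corr_block_rho`.
#' @param corr_block_rho Common within-block correlation in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `expr` (an [expression_matrix()]) and `truth`.
#' @export
simulate_expression <- function(genes, n_per_class = c(normal = 20, tumor = 20),
                                diff_genes = character(), effect_size = 1,
                                corr_blocks = list(), corr_block_rho = 0,
                                seed = 1L) {
  genes <- norm_symbols(genes)
  diff_genes <- norm_symbols(diff_genes)
  if (!all(diff_genes %in% genes))
    stop("diff_genes must be a subset of genes", call. = FALSE)
  if (abs(effect_size) >= 10) stop("|effect_size| must be < 10", call. = FALSE)
  if (corr_block_rho < 0 || corr_block_rho >= 1)
    stop("corr_block_rho must be in [0, 1)", call. = FALSE)
  if (is.null(names(n_per_class)))
    names(n_per_class) <- c("normal", "tumor")[seq_along(n_per_class)]
  n <- sum(n_per_class)
  cls <- rep(names(n_per_class), n_per_class)
  samples <- sprintf("S%03d", seq_len(n))
  vals <- with_rng_seed(seed, {
    m <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
                dimnames = list(genes, samples))
    for (block in corr_blocks) {
      block <- intersect(norm_symbols(block), genes)
      if (length(block) < 2) next
      f <- stats::rnorm(n)
      m[block, ] <- sqrt(corr_block_rho) * matrix(f, length(block), n, byrow = TRUE) +
        sqrt(1 - corr_block_rho) * m[block, ]
    }
    if (length(diff_genes) && "tumor" %in% cls)
      m[diff_genes, cls == "tumor"] <- m[diff_genes, cls == "tumor"] + effect_size
    m
  })
  expr <- expression_matrix(vals, sample_class = stats::setNames(cls, samples))
  truth <- list(diff_genes = diff_genes, effect_size = effect_size,
                corr_blocks = corr_blocks, corr_block_rho = corr_block_rho,
                seed = seed)
  list(expr = expr, truth = truth)
}

#' Simulate a survival cohort with a planted prognostic signature
#'
#' Each patient gets a latent poor/good status; poor patients' signature
#' genes are drawn near a fixed alternating template (so the
#' correlation-to-reference classifier has a recoverable target); event
#' times follow a proportional-hazards Weibull (default exponential) model
#' with the hazard multiplied by `hazard_ratio` for poor patients;
#' independent censoring is calibrated so each patient is censored with
#' probability `censor_rate`.
#'
#' @param n_patients Cohort size.
#' @param genes Gene universe for the expression sub-matrix.
#' @param signature_genes Subset of `genes` carrying the poor-prognosis
#'   template.
#' @param hazard_ratio Hazard multiplier for poor patients (> 0).
#' @param censor_rate Per-patient censoring probability in `[0, 1)`.
#' @param poor_fraction Latent poor-status probability (default 1/3).
#' @param baseline_hazard Events per month for good patients (default 0.03,
#'   median ~23 months).
#' @param shape Weibull shape (1 = exponential).
#' @param seed Integer seed.
#' @return List with `cohort` (a [survival_cohort()]) and `truth` (latent
#'   status, template, parameters).
#' @export
simulate_cohort <- function(n_patients = 150, genes, signature_genes,
                            hazard_ratio = 4, censor_rate = 0.3,
                            poor_fraction = 1 / 3, baseline_hazard = 0.03,
                            shape = 1, seed = 1L) {
  genes <- norm_symbols(genes)
  signature_genes <- norm_symbols(signature_genes)
  if (!all(signature_genes %in% genes))
    stop("signature_genes must be a subset of genes", call. = FALSE)
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  template <- 1.5 * rep_len(c(1, -1), length(signature_genes))
  names(template) <- signature_genes
  samples <- sprintf("P%04d", seq_len(n_patients))
  out <- with_rng_seed(seed, {
    poor <- stats::runif(n_patients) < poor_fraction
    m <- matrix(stats::rnorm(length(genes) * n_patients), length(genes),
                n_patients, dimnames = list(genes, samples))
    if (any(poor))
      m[signature_genes, poor] <- template +
        matrix(stats::rnorm(length(signature_genes) * sum(poor), sd = 0.5),
               length(signature_genes), sum(poor))
    rate <- baseline_hazard * ifelse(poor, hazard_ratio, 1)
    tev <- (stats::rexp(n_patients) / rate)^(1 / shape)
    if (censor_rate > 0) {
      crate <- rate * censor_rate / (1 - censor_rate)
      tc <- (stats::rexp(n_patients) / crate)^(1 / shape)
      time <- pmin(tev, tc)
      event <- as.integer(tev <= tc)
    } else {
      time <- tev
      event <- rep(1L, n_patients)
    }
    list(poor = poor, m = m, time = time, event = event)
  })
  surv <- data.frame(sample = samples, time = out$time, event = out$event,
                     stringsAsFactors = FALSE)
  cohort <- survival_cohort(surv, out$m)
  truth <- list(poor = stats::setNames(out$poor, samples),
                signature_genes = signature_genes, template = template,
                hazard_ratio = hazard_ratio, censor_rate = censor_rate,
                poor_fraction = poor_fraction,
                baseline_hazard = baseline_hazard, shape = shape, seed = seed)
  list(cohort = cohort, truth = truth)
}
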