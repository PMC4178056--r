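# Declarative run configuration and end-to-end pipeline orchestration:
# network construction -> bridgeness scoring -> optional discriminative and
# prognostic stages, with a provenance manifest. A thin command-line
# wrapper over these functions ships in inst/cli/bridgenet.R.

#' Read and validate a run configuration
#'
#' YAML key/value configuration for [run_full_pipeline()]. Required keys:
#' `ppi`, `pdi` (interaction TSVs; either may be omitted if the other is
#' present), `sensors`, `enzymes` (one-symbol-per-line lists), `seed`, and
#' `out_dir`. Optional: `coexpression` (expression TSV for edge distances),
#' `tissue_panel` + `tissue_target_samples`, `percentile_cutoff` (default
#' 40), `top_k` (default 50), `discriminate:` (`expr`, `class_a`,
#' `class_b`, `grid`, `folds`, `repeats`) and `prognosis:` (`train_expr`,
#' `train_surv`, `test_expr`, `test_surv`, `markers_from_ranking` or
#' `markers`, `folds`, `repeats`, `k`).
#'
#' @param path YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  assert_file(path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (as from [yaml::read_yaml()]).
#' @export
validate_run_config <- function(cfg) {
  fail <- function(msg) stop(structure(
    class = c("bridgenet_validation_error", "error", "condition"),
    list(message = msg, call = NULL)))
  if (is.null(cfg$ppi) && is.null(cfg$pdi))
    fail("config needs at least one of ppi/pdi")
  for (key in c("ppi", "pdi", "sensors", "enzymes", "coexpression",
                "tissue_panel")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      fail(sprintf("config file for '%s' not found: %s", key, cfg[[key]]))
  }
  if (is.null(cfg$sensors) || is.null(cfg$enzymes))
    fail("config needs sensors and enzymes files")
  if (is.null(cfg$seed)) fail("config needs a seed")
  if (is.null(cfg$out_dir)) fail("config needs out_dir")
  cfg$percentile_cutoff <- cfg$percentile_cutoff %||% 40
  cfg$top_k <- cfg$top_k %||% 50
  structure(cfg, class = "run_config")
}

.write_stamped_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bridgenet config %s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full bridge-network pipeline
#'
#' Executes network construction (interaction integration, co-expression
#' edge distances, tissue filtering, reference extraction), bridgeness
#' scoring, and the optional discriminative and prognostic stages, writing
#' the network, the bridgeness table, accuracy curves, the prognostic model
#' and a provenance manifest (all parameters, package version, seed and
#' config hash) under `out_dir`. Any stage error aborts with the stage
#' name; partial outputs are retained alongside a `FAILED` marker naming
#' the stage.
#'
#' @param config A `run_config` (see [read_run_config()]) or path to one.
#' @return Invisibly, a list with the network, the bridgeness table, and
#'   any stage results.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(unclass(config))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(config))
  stage <- "validate"
  res <- list()
  tryCatch({
    stage <- "construction"
    ppi <- if (!is.null(config$ppi)) read_interaction_table(config$ppi, "PPI")
    pdi <- if (!is.null(config$pdi)) read_interaction_table(config$pdi, "PDI")
    sensors <- norm_symbols(readLines(config$sensors, warn = FALSE))
    enzymes <- norm_symbols(readLines(config$enzymes, warn = FALSE))
    net <- integrate_interactions(ppi, pdi)
    net <- assign_node_roles(net, sensors, enzymes)
    if (!is.null(config$coexpression)) {
      expr <- read_expression_matrix(config$coexpression)
      net <- assign_edge_distances(net, expr)
    }
    if (!is.null(config$tissue_panel)) {
      panel_df <- utils::read.delim(config$tissue_panel, row.names = 1,
                                    check.names = FALSE)
      panel <- tissue_panel(as.matrix(panel_df),
                            config$tissue_target_samples)
      net <- filter_by_tissue_expression(net, panel, config$percentile_cutoff)
    }
    net <- extract_reference_network(net, sensors, enzymes)
    net_path <- file.path(out_dir, "network.tsv")
    write_network(net, net_path, "edge_tsv")
    writeLines(c(sprintf("# bridgenet config %s", hash),
                 readLines(net_path, warn = FALSE)), net_path)
    res$network <- net

    stage <- "scoring"
    tab <- rank_bridges(net, k = config$top_k)
    .write_stamped_tsv(tab, file.path(out_dir, "bridgeness.tsv"), hash)
    res$bridgeness <- tab

    if (!is.null(config$discriminate)) {
      stage <- "discriminate"
      dc <- config$discriminate
      dexpr <- zscore_normalize(read_expression_matrix(dc$expr,
                                                       class_map = NULL))
      labels <- utils::read.delim(dc$labels, stringsAsFactors = FALSE)
      lab <- stats::setNames(labels$class, labels$sample)
      a <- names(lab)[lab == dc$class_a]; b <- names(lab)[lab == dc$class_b]
      pv <- per_gene_t_tests(dexpr, a, b)
      sel <- dexpr$samples %in% c(a, b)
      two <- lab[dexpr$samples[sel]]
      sub <- expression_matrix(dexpr$values[, dexpr$samples[sel], drop = FALSE],
                               sample_class = two)
      ranked <- intersect(tab$gene, dexpr$genes)
      grid <- dc$grid %||% seq(10, min(100, length(ranked)), 10)
      curve <- cumulative_classification_cv(
        sub, ranked, two, grid = grid,
        folds = dc$folds %||% 5, repeats = dc$repeats %||% 5,
        seed = config$seed)
      base <- random_feature_baseline(
        sub, two, grid = grid, repeats = dc$random_repeats %||% 100,
        folds = dc$folds %||% 5, seed = config$seed)
      curves <- rbind(
        data.frame(k = curve$k, source = "bridge", mean_acc = curve$mean_acc,
                   ci_lo = NA, ci_hi = NA),
        data.frame(k = base$k, source = "random", mean_acc = base$mean_acc,
                   ci_lo = base$ci_lo, ci_hi = base$ci_hi))
      .write_stamped_tsv(curves, file.path(out_dir, "curves.tsv"), hash)
      res$discriminate <- list(tests = pv, curve = curve, baseline = base)
    }

    if (!is.null(config$prognosis)) {
      stage <- "prognosis"
      pc <- config$prognosis
      tr <- survival_cohort(read_survival_table(pc$train_surv),
                            read_expression_matrix(pc$train_expr))
      markers <- if (!is.null(pc$markers))
        norm_symbols(readLines(pc$markers, warn = FALSE)) else tab$gene
      model <- train_prognostic_model(
        tr, markers, folds = pc$folds %||% 5, repeats = pc$repeats %||% 100,
        k = pc$k %||% 3, seed = config$seed)
      te <- survival_cohort(read_survival_table(pc$test_surv),
                            read_expression_matrix(pc$test_expr))
      labels <- classify_by_correlation(te, model)
      ev <- evaluate_prognosis(te, labels)
      .write_stamped_tsv(
        data.frame(gene = names(model$reference_profile),
                   reference = model$reference_profile,
                   threshold = model$threshold),
        file.path(out_dir, "model.tsv"), hash)
      .write_stamped_tsv(
        data.frame(sample = names(labels), label = as.character(labels),
                   r = attr(labels, "r")),
        file.path(out_dir, "prognosis.tsv"), hash)
      res$prognosis <- list(model = model, labels = labels, evaluation = ev)
    }

    stage <- "manifest"
    manifest <- list(
      package = "bridgenet",
      version = as.character(utils::packageVersion("bridgenet")),
      config = unclass(config), config_hash = hash, seed = config$seed)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }, error = function(e) {
    writeLines(sprintf("stage: %s\n%s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
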