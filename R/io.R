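# Readers and writers for every external representation the pipeline
# touches. All other modules operate on in-memory objects only.

MISSING_TOKENS <- c("", "NA", "null")

#' Construct an expression matrix
#'
#' Gene-by-sample expression values (log-scale intensities) with an optional
#' per-sample class label (`normal`, `polyp`, `tumor` or `unknown`).
#'
#' @param values Numeric matrix, genes in rows, samples in columns; rownames
#'   are gene symbols (upper-cased), colnames sample ids.
#' @param sample_class Optional character vector of class labels, either
#'   named by sample id or in column order. Defaults to `"unknown"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `genes`, `samples`, `sample_class`.
#' @export
expression_matrix <- function(values, sample_class = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs gene rownames and sample colnames", call. = FALSE)
  storage.mode(values) <- "double"
  rownames(values) <- norm_symbols(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols; collapse before constructing", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids", call. = FALSE)
  cls <- rep("unknown", ncol(values))
  names(cls) <- colnames(values)
  if (!is.null(sample_class)) {
    if (!is.null(names(sample_class))) {
      hit <- intersect(names(sample_class), colnames(values))
      cls[hit] <- as.character(sample_class[hit])
    } else {
      stopifnot(length(sample_class) == ncol(values))
      cls[] <- as.character(sample_class)
    }
  }
  structure(
    list(values = values, genes = rownames(values),
         samples = colnames(values), sample_class = cls),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              length(x$genes), length(x$samples)))
  cat("classes:", paste(sprintf("%s=%d", names(table(x$sample_class)),
                                table(x$sample_class)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a protein interaction table
#'
#' Reads a tab-separated list of gene-symbol pairs. PPI rows are treated as
#' bidirectional interactions, PDI rows as unidirectional interactions from
#' a transcription factor to its target gene.
#'
#' @param path TSV file with at least two columns (source, target); lines
#'   starting with `#` are ignored; a header row whose first field is
#'   `source` is skipped.
#' @param kind `"PPI"` or `"PDI"`; fixes the `directed` flag (PPI `FALSE`,
#'   PDI `TRUE`).
#' @return A data.frame with columns `source`, `target`, `kind`, `directed`,
#'   one row per input row (duplicates preserved).
#' @export
read_interaction_table <- function(path, kind = c("PPI", "PDI")) {
  kind <- match.arg(kind)
  assert_file(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^source\\b", lines[[1]], ignore.case = TRUE))
    lines <- lines[-1L]
  if (!length(lines)) {
    return(data.frame(source = character(), target = character(),
                      kind = character(), directed = logical(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad))
    stop(sprintf("malformed interaction row at line %d of %s: fewer than 2 columns",
                 bad[[1]], path), call. = FALSE)
  data.frame(
    source = norm_symbols(vapply(parts, `[[`, "", 1L)),
    target = norm_symbols(vapply(parts, `[[`, "", 2L)),
    kind = kind,
    directed = kind == "PDI",
    stringsAsFactors = FALSE)
}

.parse_numeric_cells <- function(cells, path) {
  cells <- trimws(cells)
  miss <- cells %in% MISSING_TOKENS
  out <- suppressWarnings(as.numeric(cells))
  bad <- !miss & is.na(out)
  if (any(bad))
    stop(sprintf("non-numeric expression value '%s' in %s",
                 cells[which(bad)[1]], path), call. = FALSE)
  out[miss] <- NA_real_
  out
}

#' Read a gene-by-sample expression matrix
#'
#' Accepts either a plain TSV (first column gene symbol, header row of
#' sample ids) or a GEO series-matrix-style file in which the table is
#' delimited by `!series_matrix_table_begin` / `!series_matrix_table_end`
#' markers. Duplicate gene symbols are collapsed by their mean (messaged).
#' Missing values may be coded as the empty string, `NA` or `null`; any
#' other non-numeric cell is an error.
#'
#' @param path Input file.
#' @param class_map Optional named character vector mapping sample id to
#'   class label; unmapped samples get `"unknown"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, class_map = NULL) {
  assert_file(path)
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  if (length(begin)) {
    end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (!length(end)) stop("series-matrix begin marker without end marker",
                           call. = FALSE)
    lines <- lines[(begin[1] + 1L):(end[1] - 1L)]
  }
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("expression table has no data rows", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  samples <- gsub('^"|"$', "", header[-1L])
  body <- parts[-1L]
  genes <- norm_symbols(gsub('^"|"$', "",
                             vapply(body, `[[`, "", 1L)))
  vals <- t(vapply(body, function(p) {
    if (length(p) != length(header))
      stop(sprintf("row with %d fields, expected %d in %s",
                   length(p), length(header), path), call. = FALSE)
    .parse_numeric_cells(p[-1L], path)
  }, numeric(length(samples))))
  if (length(samples) == 1L) vals <- matrix(vals, ncol = 1L)
  rownames(vals) <- genes
  colnames(vals) <- samples
  if (anyDuplicated(genes)) {
    message(sprintf("collapsing %d duplicated gene symbols by mean",
                    sum(duplicated(genes))))
    sums <- rowsum(ifelse(is.na(vals), 0, vals), genes)
    cnts <- rowsum((!is.na(vals)) * 1, genes)
    vals <- sums / cnts
    vals[cnts == 0] <- NA_real_
    # rowsum sorts groups; keep first-appearance order of the unique symbols
    vals <- vals[unique(genes), , drop = FALSE]
  }
  expression_matrix(vals, sample_class = class_map)
}

#' Write an expression matrix as TSV
#'
#' @param expr An [expression_matrix()].
#' @param path Output file; first column `gene`, then one column per sample.
#' @param digits Decimal places written (default 6).
#' @export
write_expression_matrix <- function(expr, path, digits = 6) {
  stopifnot(inherits(expr, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", expr$samples), collapse = "\t"), con)
  fmt <- paste0("%.", digits, "f")
  for (i in seq_along(expr$genes)) {
    v <- expr$values[i, ]
    cells <- ifelse(is.na(v), "NA", sprintf(fmt, v))
    writeLines(paste(c(expr$genes[i], cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a survival table
#'
#' TSV with columns `sample`, `time` (non-negative, months) and `event`
#' (1 = relapse/death observed, 0 = censored).
#'
#' @param path Input TSV (header required).
#' @return data.frame with columns `sample`, `time`, `event` (integer 0/1).
#' @export
read_survival_table <- function(path) {
  assert_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival table needs columns sample, time, event", call. = FALSE)
  df <- df[need]
  df$sample <- as.character(df$sample)
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  if (anyDuplicated(df$sample)) stop("duplicated sample ids", call. = FALSE)
  if (any(is.na(df$time)) || any(df$time < 0))
    stop("survival times must be non-negative", call. = FALSE)
  if (!all(df$event %in% c(0L, 1L)))
    stop("event must be 0 or 1", call. = FALSE)
  df
}

# ---- network serialization ------------------------------------------------

#' Write a bridge network to file
#'
#' Three dialects are supported. `edge_tsv` writes `source`, `target`,
#' `kind`, `distance` (6-decimal fixed) preceded by `# node <name> <role>`
#' comment lines so that roles and isolated nodes survive the round trip.
#' `graphml` uses igraph's GraphML writer with `role`, `kind` and `distance`
#' attributes. `sif` writes standard simple-interaction-format lines with
#' relation tokens `pp` (PPI) and `pd` (PDI); roles and distances ride along
#' in comment lines (plain SIF consumers ignore them).
#'
#' @param network A `bridge_network`.
#' @param path Output file.
#' @param dialect One of `"edge_tsv"`, `"graphml"`, `"sif"`.
#' @return `path`, invisibly. `read_network(write_network(n))` reproduces
#'   node set, edge set, roles and distances at 6-decimal precision.
#' @export
write_network <- function(network, path, dialect = c("edge_tsv", "graphml", "sif")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(network, "bridge_network"))
  g <- network$graph
  ed <- igraph::as_data_frame(g, what = "edges")
  if (nrow(ed)) ed$distance <- round(ed$distance, 6)
  roles <- igraph::vertex_attr(g, "role") %||% rep("intermediate", igraph::vcount(g))
  nodes <- igraph::V(g)$name
  if (dialect == "graphml") {
    g2 <- g
    if (igraph::ecount(g2))
      igraph::E(g2)$distance <- round(igraph::E(g2)$distance, 6)
    igraph::write_graph(g2, path, format = "graphml")
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(nodes))
    writeLines(sprintf("# node\t%s\t%s", nodes[i], roles[i]), con)
  if (dialect == "edge_tsv") {
    writeLines("source\ttarget\tkind\tdistance", con)
    if (nrow(ed))
      writeLines(sprintf("%s\t%s\t%s\t%.6f", ed$from, ed$to, ed$kind, ed$distance), con)
  } else { # sif
    if (nrow(ed)) {
      for (i in seq_len(nrow(ed)))
        writeLines(sprintf("# distance\t%s\t%s\t%.6f", ed$from[i], ed$to[i], ed$distance[i]), con)
      tok <- ifelse(ed$kind == "PDI", "pd", "pp")
      writeLines(sprintf("%s\t%s\t%s", ed$from, tok, ed$to), con)
    }
  }
  invisible(path)
}

#' Read a bridge network written by [write_network()]
#'
#' @param path Input file.
#' @param dialect One of `"edge_tsv"`, `"graphml"`, `"sif"`.
#' @return A `bridge_network`.
#' @export
read_network <- function(path, dialect = c("edge_tsv", "graphml", "sif")) {
  dialect <- match.arg(dialect)
  assert_file(path)
  if (dialect == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(new_bridge_network(g, provenance = list(source = path)))
  }
  lines <- readLines(path, warn = FALSE)
  nodeln <- grep("^# node\t", lines)
  distln <- grep("^# distance\t", lines)
  nd <- do.call(rbind, strsplit(sub("^# node\t", "", lines[nodeln]), "\t"))
  roles <- if (length(nodeln)) stats::setNames(nd[, 2], nd[, 1]) else character()
  body <- lines[setdiff(seq_along(lines), c(nodeln, distln))]
  body <- body[nzchar(trimws(body)) & !grepl("^\\s*#", body)]
  if (dialect == "edge_tsv") {
    stopifnot(length(body) >= 1L)  # header always written
    body <- body[-1L]
    if (length(body)) {
      p <- do.call(rbind, strsplit(body, "\t"))
      ed <- data.frame(from = p[, 1], to = p[, 2], kind = p[, 3],
                       distance = as.numeric(p[, 4]), stringsAsFactors = FALSE)
    } else ed <- NULL
  } else {
    if (length(body)) {
      p <- do.call(rbind, strsplit(body, "\t"))
      dmap <- if (length(distln)) {
        dp <- do.call(rbind, strsplit(sub("^# distance\t", "", lines[distln]), "\t"))
        stats::setNames(as.numeric(dp[, 3]), paste(dp[, 1], dp[, 2]))
      } else NULL
      key <- paste(p[, 1], p[, 3])
      ed <- data.frame(from = p[, 1], to = p[, 3],
                       kind = ifelse(p[, 2] == "pd", "PDI", "PPI"),
                       distance = if (is.null(dmap)) 1 else unname(dmap[key]),
                       stringsAsFactors = FALSE)
    } else ed <- NULL
  }
  verts <- data.frame(name = names(roles),
                      role = unname(roles), stringsAsFactors = FALSE)
  if (is.null(ed))
    ed <- data.frame(from = character(), to = character(),
                     kind = character(), distance = numeric())
  extra <- setdiff(unique(c(ed$from, ed$to)), verts$name)
  if (length(extra))
    verts <- rbind(verts, data.frame(name = extra, role = "intermediate"))
  g <- igraph::graph_from_data_frame(ed, directed = TRUE, vertices = verts)
  new_bridge_network(g, provenance = list(source = path))
}
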