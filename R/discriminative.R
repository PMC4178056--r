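# Discriminative evaluation of gene sets: Z-score normalization, per-gene
# Student t-tests, one-sided KS tests on p-value distributions, marker-count
# selection, and cumulative cross-validated classification with random
# feature baselines.

#' Gene-wise Z-score normalization
#'
#' Centers and scales each gene row to mean 0 and standard deviation 1.
#' Rows with zero variance become all-zero and are flagged in the
#' `constant_genes` attribute.
#'
#' @param expr An [expression_matrix()] with at least two samples.
#' @return The normalized [expression_matrix()]. Idempotent.
#' @export
zscore_normalize <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (ncol(expr$values) < 2L)
    stop("Z-score normalization needs >= 2 samples", call. = FALSE)
  m <- rowMeans(expr$values, na.rm = TRUE)
  s <- apply(expr$values, 1, stats::sd, na.rm = TRUE)
  const <- !is.na(s) & s == 0
  s[const | is.na(s)] <- 1
  out <- (expr$values - m) / s
  out[const, ] <- 0
  res <- expression_matrix(out, sample_class = expr$sample_class)
  attr(res, "constant_genes") <- expr$genes[const]
  res
}

#' Per-gene two-sample Student t-tests
#'
#' Classical pooled-variance t-test of each gene between two sample groups,
#' two-sided p-values from the t distribution with `n1 + n2 - 2` degrees of
#' freedom. Genes with zero pooled variance are flagged and assigned
#' `p = 1` (undefined test).
#'
#' @param expr An [expression_matrix()].
#' @param samples_a,samples_b Sample id vectors for the two groups, each of
#'   size >= 2.
#' @param welch Use Welch's unequal-variance test instead (default `FALSE`).
#' @return A `pvalue_set` data.frame: `gene`, `t`, `p`, `flag`; attributes
#'   `n1`, `n2`.
#' @export
per_gene_t_tests <- function(expr, samples_a, samples_b, welch = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"))
  samples_a <- intersect(as.character(samples_a), expr$samples)
  samples_b <- intersect(as.character(samples_b), expr$samples)
  n1 <- length(samples_a); n2 <- length(samples_b)
  if (n1 < 2L || n2 < 2L)
    stop("both groups need >= 2 samples", call. = FALSE)
  A <- expr$values[, samples_a, drop = FALSE]
  B <- expr$values[, samples_b, drop = FALSE]
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- apply(A, 1, stats::var); v2 <- apply(B, 1, stats::var)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tt <- (m1 - m2) / sqrt(se2)
    flag <- !is.finite(tt)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- rep(n1 + n2 - 2, length(sp2))
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    flag <- sp2 == 0
  }
  p <- 2 * stats::pt(-abs(tt), df)
  tt[flag] <- NA_real_
  p[flag] <- 1
  out <- data.frame(gene = expr$genes, t = unname(tt), p = unname(p),
                    flag = unname(flag), stringsAsFactors = FALSE)
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  class(out) <- c("pvalue_set", "data.frame")
  out
}

#' One-sided KS test for a left-shifted p-value distribution
#'
#' Two-sample Kolmogorov-Smirnov test of whether the selected genes'
#' p-values are stochastically smaller than the background p-values (their
#' empirical CDF lies above the background's), i.e. whether the selected
#' set is more discriminative than background. Asymptotic p-value.
#'
#' @param selected_p,background_p Non-empty numeric vectors of p-values.
#' @return List with `statistic` (the one-sided D+ statistic) and `p.value`.
#' @export
ks_shift_test <- function(selected_p, background_p) {
  if (!length(selected_p) || !length(background_p))
    stop("both p-value samples must be non-empty", call. = FALSE)
  res <- suppressWarnings(
    stats::ks.test(selected_p, background_p, alternative = "greater",
                   exact = FALSE))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Choose the marker count minimizing the KS shift p-value
#'
#' For each count `k` on the grid, tests whether the top-`k` ranked genes'
#' p-values are left-shifted relative to background and returns the count
#' with the smallest KS p-value (ties go to the smallest count).
#'
#' @param ranked_genes Genes in rank order (best first), covering
#'   `max(grid)`.
#' @param pvalues Named numeric vector of per-gene p-values.
#' @param background_p Background p-value distribution.
#' @param grid Candidate counts, default `seq(10, 100, 10)`.
#' @return List with `best_k` and the per-count `table` (k, statistic, p).
#' @export
choose_marker_count <- function(ranked_genes, pvalues, background_p,
                                grid = seq(10, 100, by = 10)) {
  if (!length(grid)) stop("empty grid", call. = FALSE)
  grid <- sort(unique(as.integer(grid)))
  if (length(ranked_genes) < max(grid))
    stop("ranked gene list shorter than max(grid)", call. = FALSE)
  tab <- do.call(rbind, lapply(grid, function(k) {
    sel <- pvalues[ranked_genes[seq_len(k)]]
    res <- ks_shift_test(sel[!is.na(sel)], background_p)
    data.frame(k = k, statistic = res$statistic, p = res$p.value)
  }))
  list(best_k = tab$k[which.min(tab$p)], table = tab)
}

# ---- ridge-penalized logistic regression ---------------------------------

# IRLS fit of logistic regression with a fixed small ridge penalty on the
# non-intercept coefficients, so perfectly separable training folds do not
# diverge. Accepts single-column designs.
.ridge_logistic_fit <- function(X, y, lambda = 1e-3, maxit = 50, tol = 1e-8) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    wv <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / wv
    XtW <- t(X1 * wv)
    new <- solve(XtW %*% X1 + pen, XtW %*% z)
    if (max(abs(new - beta)) < tol) { beta <- new; break }
    beta <- new
  }
  drop(beta)
}

.ridge_logistic_predict <- function(beta, X) {
  stats::plogis(drop(cbind(1, X) %*% beta)) > 0.5
}

# Stratified fold ids: per class, shuffled samples assigned round-robin.
.stratified_folds <- function(labels, folds) {
  ids <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    ids[idx] <- rep_len(seq_len(folds), length(idx))
  }
  ids
}

.cv_accuracy <- function(X, y, folds, repeats, lambda) {
  accs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fid <- .stratified_folds(y, folds)
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fid != f; te <- !tr
      if (!any(te)) next
      beta <- .ridge_logistic_fit(X[tr, , drop = FALSE], y[tr], lambda)
      pred <- .ridge_logistic_predict(beta, X[te, , drop = FALSE])
      correct <- correct + sum(pred == (y[te] == 1))
    }
    accs[r] <- correct / length(y)
  }
  accs
}

.two_class_labels <- function(expr, labels) {
  labels <- if (!is.null(names(labels))) labels[expr$samples] else {
    stopifnot(length(labels) == length(expr$samples))
    stats::setNames(labels, expr$samples)
  }
  if (any(is.na(labels))) stop("labels missing for some samples", call. = FALSE)
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L) stop("exactly two classes required", call. = FALSE)
  as.integer(as.character(labels) == lv[2])
}

#' Cumulative cross-validated classification accuracy
#'
#' For each feature count `k` on the grid, fits a ridge-penalized logistic
#' regression on the top-`k` ranked genes' expression within each training
#' fold of a stratified `folds`-fold cross-validation, repeated `repeats`
#' times, and reports the mean classification accuracy (correct/total,
#' pooled over folds, averaged over repeats).
#'
#' @param expr An [expression_matrix()] (normalize first if desired).
#' @param ranked_genes Genes in rank order; must be present in `expr`.
#' @param labels Two-class sample labels (named by sample id, or in column
#'   order).
#' @param grid Feature counts, all >= 1; default `seq(10, 100, 10)` clipped
#'   to the ranked list length.
#' @param folds,repeats Cross-validation design (default 5 x 5).
#' @param seed Integer seed driving fold assignment.
#' @param lambda Fixed ridge penalty (default 1e-3).
#' @return An `accuracy_curve` data.frame: `k`, `mean_acc`; per-repeat
#'   accuracies in attribute `repeat_acc`.
#' @export
cumulative_classification_cv <- function(expr, ranked_genes, labels,
                                         grid = NULL, folds = 5, repeats = 5,
                                         seed = 1L, lambda = 1e-3) {
  stopifnot(inherits(expr, "expression_matrix"))
  ranked_genes <- norm_symbols(ranked_genes)
  miss <- setdiff(ranked_genes, expr$genes)
  if (length(miss))
    stop(sprintf("ranked genes absent from expression: %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  grid <- grid %||% seq(10, min(100, length(ranked_genes)), by = 10)
  grid <- sort(unique(as.integer(grid)))
  if (!length(grid) || any(grid < 1))
    stop("feature counts must be >= 1", call. = FALSE)
  if (max(grid) > length(ranked_genes))
    stop("grid exceeds ranked gene list", call. = FALSE)
  y <- .two_class_labels(expr, labels)
  if (length(y) < folds) stop("fewer samples than folds", call. = FALSE)
  rep_acc <- matrix(NA_real_, length(grid), repeats)
  with_rng_seed(seed, {
    for (gi in seq_along(grid)) {
      genes <- ranked_genes[seq_len(grid[gi])]
      X <- t(expr$values[genes, , drop = FALSE])
      rep_acc[gi, ] <- .cv_accuracy(X, y, folds, repeats, lambda)
    }
  })
  out <- data.frame(k = grid, mean_acc = rowMeans(rep_acc))
  attr(out, "repeat_acc") <- rep_acc
  class(out) <- c("accuracy_curve", "data.frame")
  out
}

#' Random-feature classification baseline with 95% confidence interval
#'
#' For each feature count, draws `repeats` random gene sets (without
#' replacement), evaluates each with the same cross-validation as
#' [cumulative_classification_cv()], and reports the mean accuracy with a
#' normal-approximation 95% confidence interval over the repeat means.
#'
#' @inheritParams cumulative_classification_cv
#' @param repeats Number of random gene draws per grid point (default 100).
#' @param cv_repeats Cross-validation repeats per draw (default 1).
#' @return An `accuracy_curve` data.frame: `k`, `mean_acc`, `ci_lo`,
#'   `ci_hi`. With `repeats = 1` the interval is degenerate and flagged in
#'   attribute `degenerate_ci`.
#' @export
random_feature_baseline <- function(expr, labels, grid, repeats = 100,
                                    folds = 5, cv_repeats = 1, seed = 1L,
                                    lambda = 1e-3) {
  stopifnot(inherits(expr, "expression_matrix"))
  grid <- sort(unique(as.integer(grid)))
  if (!length(grid) || any(grid < 1))
    stop("feature counts must be >= 1", call. = FALSE)
  if (max(grid) > length(expr$genes))
    stop("grid exceeds gene universe", call. = FALSE)
  y <- .two_class_labels(expr, labels)
  if (length(y) < folds) stop("fewer samples than folds", call. = FALSE)
  out <- data.frame(k = grid, mean_acc = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_)
  with_rng_seed(seed, {
    for (gi in seq_along(grid)) {
      means <- numeric(repeats)
      for (r in seq_len(repeats)) {
        genes <- sample(expr$genes, grid[gi])
        X <- t(expr$values[genes, , drop = FALSE])
        means[r] <- mean(.cv_accuracy(X, y, folds, cv_repeats, lambda))
      }
      m <- mean(means)
      half <- if (repeats > 1) 1.96 * stats::sd(means) / sqrt(repeats) else 0
      out$mean_acc[gi] <- m
      out$ci_lo[gi] <- m - half
      out$ci_hi[gi] <- m + half
    }
  })
  attr(out, "degenerate_ci") <- repeats == 1
  class(out) <- c("accuracy_curve", "data.frame")
  out
}
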