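# Prognostic evaluation: unsupervised patient subgrouping with
# Kaplan-Meier / log-rank comparison, and the supervised
# correlation-to-reference classifier with cross-validated threshold
# selection.

#' Construct a survival cohort
#'
#' @param survival data.frame with columns `sample`, `time` (months,
#'   non-negative), `event` (1 observed, 0 censored); ids unique.
#' @param expr Gene-by-sample numeric matrix or [expression_matrix()]; its
#'   samples must be a subset of the survival table's.
#' @return An object of class `survival_cohort`: list with `survival` and
#'   `expr` (genes x samples matrix), samples aligned.
#' @export
survival_cohort <- function(survival, expr) {
  need <- c("sample", "time", "event")
  stopifnot(is.data.frame(survival), all(need %in% names(survival)))
  survival <- survival[need]
  survival$sample <- as.character(survival$sample)
  if (anyDuplicated(survival$sample))
    stop("duplicated sample ids in survival table", call. = FALSE)
  if (any(survival$time < 0)) stop("negative survival time", call. = FALSE)
  if (!all(survival$event %in% c(0, 1)))
    stop("event must be 0/1", call. = FALSE)
  if (inherits(expr, "expression_matrix")) expr <- expr$values
  expr <- as.matrix(expr)
  rownames(expr) <- norm_symbols(rownames(expr))
  if (!all(colnames(expr) %in% survival$sample))
    stop("expression samples not covered by survival table", call. = FALSE)
  survival <- survival[match(colnames(expr), survival$sample), , drop = FALSE]
  rownames(survival) <- NULL
  structure(list(survival = survival, expr = expr), class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("survival_cohort: %d patients, %d genes, %d events (%.0f%% censored)\n",
              nrow(x$survival), nrow(x$expr), sum(x$survival$event),
              100 * mean(1 - x$survival$event)))
  invisible(x)
}

#' Unsupervised hierarchical patient subgroups
#'
#' Agglomerative clustering of patients on Euclidean distances between
#' their expression profiles, tree cut into `k` groups.
#'
#' @param expr Gene-by-sample matrix (typically restricted to marker genes
#'   and Z-normalized upstream) or [expression_matrix()].
#' @param k Number of subgroups, >= 2.
#' @param linkage Agglomeration method (default `"complete"`).
#' @return Integer subgroup labels named by sample id.
#' @export
hierarchical_subgroups <- function(expr, k = 3, linkage = "complete") {
  if (inherits(expr, "expression_matrix")) expr <- expr$values
  expr <- as.matrix(expr)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (ncol(expr) < k) stop("fewer samples than subgroups", call. = FALSE)
  hc <- stats::hclust(stats::dist(t(expr), method = "euclidean"),
                      method = linkage)
  stats::cutree(hc, k = k)
}

.groups_from_labels <- function(records, labels) {
  labels <- if (!is.null(names(labels))) labels[records$sample] else {
    stopifnot(length(labels) == nrow(records))
    stats::setNames(labels, records$sample)
  }
  if (any(is.na(labels))) stop("labels missing for some samples", call. = FALSE)
  factor(as.character(labels))
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator of the survival function within each group;
#' with zero censoring it equals the empirical survival function.
#'
#' @param records Survival data.frame (`sample`, `time`, `event`).
#' @param labels Group labels, named by sample or in row order.
#' @return A [survival::survfit] object.
#' @export
km_estimate <- function(records, labels) {
  grp <- .groups_from_labels(records, labels)
  if (any(table(grp) == 0)) stop("empty group", call. = FALSE)
  df <- data.frame(time = records$time, event = records$event, group = grp)
  survival::survfit(survival::Surv(time, event) ~ group, data = df)
}

#' Log-rank test across groups
#'
#' Standard k-group log-rank test (observed minus hypergeometric-expected
#' events accumulated over event times), chi-square with k-1 degrees of
#' freedom.
#'
#' @inheritParams km_estimate
#' @return List with `statistic`, `df`, `p.value`.
#' @export
logrank_test <- function(records, labels) {
  grp <- .groups_from_labels(records, labels)
  if (nlevels(grp) < 2) stop("log-rank needs >= 2 groups", call. = FALSE)
  df <- data.frame(time = records$time, event = records$event, group = grp)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(sd$n)
  list(statistic = unname(sd$chisq), df = k - 1L,
       p.value = stats::pchisq(sd$chisq, k - 1L, lower.tail = FALSE))
}

# Restricted mean survival time of one group's KM curve up to tau.
.rmst <- function(time, event, tau) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tt <- c(0, fit$time[fit$time <= tau], tau)
  ss <- c(1, fit$surv[fit$time <= tau])
  sum(diff(tt) * ss)
}

#' Identify the poorest-prognosis group
#'
#' The group with the smallest restricted mean survival (area under its
#' Kaplan-Meier curve) up to the last observation time common to all
#' groups; deterministic ties go to the smallest group label. An
#' alternative rule, the lowest KM estimate at a fixed horizon, is
#' available via `method = "km_at_horizon"`.
#'
#' @inheritParams km_estimate
#' @param method `"rmst"` (default) or `"km_at_horizon"`.
#' @param horizon Horizon time for `"km_at_horizon"`; defaults to the
#'   common restriction time.
#' @return The poorest group's label (same level set as `labels`).
#' @export
identify_poorest_group <- function(records, labels, method = c("rmst", "km_at_horizon"),
                                   horizon = NULL) {
  method <- match.arg(method)
  grp <- .groups_from_labels(records, labels)
  if (nlevels(grp) < 2) stop("needs >= 2 groups", call. = FALSE)
  tau <- min(tapply(records$time, grp, max))
  tau <- horizon %||% tau
  score <- vapply(levels(grp), function(gl) {
    sel <- grp == gl
    if (method == "rmst") .rmst(records$time[sel], records$event[sel], tau)
    else {
      fit <- survival::survfit(survival::Surv(records$time[sel], records$event[sel]) ~ 1)
      s <- c(1, fit$surv)[findInterval(tau, c(0, fit$time))]
      s
    }
  }, numeric(1))
  levels(grp)[which.min(score)]  # which.min takes the first = smallest label
}

#' Correlation-to-reference prognostic classification
#'
#' Each patient's marker-gene expression vector is correlated (Pearson)
#' with the model's reference profile (the mean profile of the training
#' poorest-prognosis subgroup); the patient is labelled `poor` when
#' `r > threshold`, else `good`.
#'
#' @param x A `survival_cohort` or gene-by-sample matrix.
#' @param model A `prognostic_model` from [train_prognostic_model()], or any
#'   list with `reference_profile` (named numeric) and `threshold`.
#' @return Named character vector of `"poor"` / `"good"`; per-patient
#'   correlations in attribute `r`. Fewer than 3 shared marker genes is an
#'   error; missing genes are dropped pairwise (messaged).
#' @export
classify_by_correlation <- function(x, model) {
  expr <- if (inherits(x, "survival_cohort")) x$expr else as.matrix(x)
  ref <- model$reference_profile
  shared <- intersect(names(ref), rownames(expr))
  if (length(shared) < 3)
    stop("fewer than 3 shared marker genes; correlation meaningless",
         call. = FALSE)
  if (length(shared) < length(ref))
    message(sprintf("%d marker genes missing from test expression dropped",
                    length(ref) - length(shared)))
  r <- apply(expr[shared, , drop = FALSE], 2, function(v)
    suppressWarnings(stats::cor(v, ref[shared])))
  lab <- ifelse(!is.na(r) & r > model$threshold, "poor", "good")
  attr(lab, "r") <- r
  lab
}

# One training pass on a sample subset: cluster, find the poorest subgroup,
# return its mean marker profile.
.reference_from_training <- function(cohort, markers, samples, k, linkage) {
  ex <- cohort$expr[markers, samples, drop = FALSE]
  cl <- hierarchical_subgroups(ex, k = k, linkage = linkage)
  rec <- cohort$survival[match(samples, cohort$survival$sample), , drop = FALSE]
  poorest <- identify_poorest_group(rec, cl)
  members <- samples[cl == as.integer(poorest)]
  rowMeans(cohort$expr[markers, members, drop = FALSE])
}

#' Cross-validated selection of the correlation threshold
#'
#' Per repeat: a random 5-fold split of the training cohort; within each
#' fold the reference profile is rebuilt from that fold's training portion
#' (re-clustering and poorest-group identification on the portion alone)
#' and the held-out patients' correlations to it are recorded; held-out
#' assignments are pooled across folds, a two-group log-rank p-value is
#' computed at every grid threshold, and the repeat's best threshold is the
#' arg-min p (ties to the smaller, more inclusive threshold). The returned
#' threshold is the mean of the per-repeat best thresholds.
#'
#' @param cohort A `survival_cohort` (training data).
#' @param markers Marker gene symbols (subset of the cohort's genes).
#' @param grid Candidate thresholds in `[-1, 1]`; default
#'   `seq(-0.95, 0.95, 0.05)`.
#' @param folds,repeats CV design (defaults 5 and 100).
#' @param k Number of clusters for subgrouping (default 3).
#' @param seed Integer seed.
#' @param linkage Clustering linkage.
#' @return Mean best threshold; per-repeat values in attribute
#'   `repeat_thresholds`. Repeats whose folds cannot produce a poorest
#'   group are skipped (messaged); more than 50% skipped is an error.
#' @export
cv_select_threshold <- function(cohort, markers, grid = seq(-0.95, 0.95, by = 0.05),
                                folds = 5, repeats = 100, k = 3, seed = 1L,
                                linkage = "complete") {
  stopifnot(inherits(cohort, "survival_cohort"))
  markers <- intersect(norm_symbols(markers), rownames(cohort$expr))
  if (length(markers) < 3) stop("fewer than 3 markers in cohort", call. = FALSE)
  grid <- sort(unique(grid))
  if (!length(grid) || any(grid < -1 | grid > 1))
    stop("grid must lie in [-1, 1]", call. = FALSE)
  samples <- cohort$survival$sample
  n <- length(samples)
  if (n < folds * k) stop("cohort too small for the CV design", call. = FALSE)
  best <- rep(NA_real_, repeats)
  with_rng_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      fid <- sample(rep_len(seq_len(folds), n))
      r_held <- rep(NA_real_, n)
      ok <- TRUE
      for (f in seq_len(folds)) {
        tr <- samples[fid != f]; te <- samples[fid == f]
        if (length(tr) < k || !length(te)) { ok <- FALSE; break }
        ref <- tryCatch(
          .reference_from_training(cohort, markers, tr, k, linkage),
          error = function(e) NULL)
        if (is.null(ref)) { ok <- FALSE; break }
        r_held[fid == f] <- apply(cohort$expr[markers, te, drop = FALSE], 2,
                                  function(v) suppressWarnings(stats::cor(v, ref)))
      }
      if (!ok || any(is.na(r_held))) next
      pvals <- vapply(grid, function(thr) {
        lab <- ifelse(r_held > thr, "poor", "good")
        if (length(unique(lab)) < 2) return(Inf)
        logrank_test(cohort$survival, stats::setNames(lab, samples))$p.value
      }, numeric(1))
      best[rep_i] <- grid[which.min(pvals)]
    }
  })
  skipped <- sum(is.na(best))
  if (skipped)
    message(sprintf("%d/%d CV repeats skipped", skipped, repeats))
  if (skipped > repeats / 2)
    stop("more than half of CV repeats failed", call. = FALSE)
  out <- mean(best, na.rm = TRUE)
  attr(out, "repeat_thresholds") <- best
  out
}

#' Train the correlation-to-reference prognostic model
#'
#' Clusters the full training cohort on the marker genes, identifies the
#' poorest-prognosis subgroup, takes its mean marker profile as the
#' reference, and selects the correlation threshold by
#' [cv_select_threshold()].
#'
#' @inheritParams cv_select_threshold
#' @return A `prognostic_model`: list with `reference_profile`, `threshold`,
#'   `markers` and `provenance` (seed, repeats, folds, grid, k, linkage).
#' @export
train_prognostic_model <- function(cohort, markers, grid = seq(-0.95, 0.95, by = 0.05),
                                   folds = 5, repeats = 100, k = 3, seed = 1L,
                                   linkage = "complete") {
  stopifnot(inherits(cohort, "survival_cohort"))
  markers0 <- norm_symbols(markers)
  markers <- intersect(markers0, rownames(cohort$expr))
  if (length(markers) < length(markers0))
    warning(sprintf("%d markers absent from training expression dropped",
                    length(markers0) - length(markers)), call. = FALSE)
  ref <- .reference_from_training(cohort, markers, cohort$survival$sample,
                                  k, linkage)
  thr <- cv_select_threshold(cohort, markers, grid = grid, folds = folds,
                             repeats = repeats, k = k, seed = seed,
                             linkage = linkage)
  structure(list(
    reference_profile = ref,
    threshold = as.numeric(thr),
    markers = markers,
    provenance = list(seed = seed, repeats = repeats, folds = folds,
                      grid = grid, k = k, linkage = linkage)),
    class = "prognostic_model")
}

#' @export
print.prognostic_model <- function(x, ...) {
  cat(sprintf("prognostic_model: %d markers, threshold %.3f\n",
              length(x$markers), x$threshold))
  invisible(x)
}

#' Evaluate prognostic separation on a test cohort
#'
#' Thin composition of [logrank_test()] and [km_estimate()] over predicted
#' (or any categorical) labels.
#'
#' @param cohort A `survival_cohort`.
#' @param labels Group labels named by sample (e.g. from
#'   [classify_by_correlation()], or a clinical covariate column).
#' @return List with `logrank` (statistic, df, p.value) and `km`
#'   ([survival::survfit]).
#' @export
evaluate_prognosis <- function(cohort, labels) {
  stopifnot(inherits(cohort, "survival_cohort"))
  list(logrank = logrank_test(cohort$survival, labels),
       km = km_estimate(cohort$survival, labels))
}
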