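surv_df <- function(time, event, sample = NULL) {
  data.frame(sample = sample %||% sprintf("p%02d", seq_along(time)),
             time = time, event = event, stringsAsFactors = FALSE)
}

test_that("survival cohorts validate and align expression to survival", {
  sv <- surv_df(c(5, 10, 15), c(1, 0, 1))
  ex <- matrix(rnorm(6), 2, 3, dimnames = list(c("G1", "G2"), sv$sample))
  co <- survival_cohort(sv, ex[, c(3, 1, 2)])
  expect_equal(co$survival$sample, colnames(co$expr))
  expect_error(survival_cohort(surv_df(c(1, 1), c(1, 1), c("a", "a")),
                               ex[, 1:2]), "duplicated")
  expect_error(survival_cohort(surv_df(-1, 1, "a"),
                               matrix(1, 1, 1, dimnames = list("G1", "a"))),
               "negative")
})

test_that("hierarchical subgroups recover well-separated patient blobs", {
  withr::with_seed(21, {
    centers <- list(rep(0, 10), rep(6, 10), rep(-6, 10))
    cols <- list()
    truth <- integer()
    for (b in 1:3) for (i in 1:30) {
      cols[[length(cols) + 1]] <- centers[[b]] + rnorm(10, sd = 0.5)
      truth <- c(truth, b)
    }
    m <- do.call(cbind, cols)
    dimnames(m) <- list(paste0("G", 1:10), sprintf("s%03d", 1:90))
    cl <- hierarchical_subgroups(m, k = 3)
    # identical partition up to renaming
    expect_equal(length(unique(paste(cl, truth))), 3L)
  })
  m2 <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("G", 1:3), paste0("s", 1:4)))
  expect_equal(length(unique(hierarchical_subgroups(m2, k = 4))), 4L)
  # duplicated sample rows always co-cluster
  m3 <- cbind(m2, s5 = m2[, "s1"])
  cl3 <- hierarchical_subgroups(m3, k = 3)
  expect_equal(unname(cl3["s1"]), unname(cl3["s5"]))
  expect_error(hierarchical_subgroups(m2, k = 1), ">= 2")
})

test_that("Kaplan-Meier estimates match hand-computed product-limit tables", {
  # no censoring: S steps 2/3, 1/3, 0
  fit <- km_estimate(surv_df(c(1, 2, 3), c(1, 1, 1)), rep("g", 3))
  expect_equal(fit$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)

  # all censored: S identically 1
  fit2 <- km_estimate(surv_df(c(1, 2, 3), c(0, 0, 0)), rep("g", 3))
  expect_true(all(fit2$surv == 1))

  # 6-subject mixed-censoring hand computation:
  # times 1, 2+, 3, 4, 4+, 5 -> S = 5/6, 5/8, 5/12, 0 at event times
  fit3 <- km_estimate(surv_df(c(1, 2, 3, 4, 4, 5), c(1, 0, 1, 1, 0, 1)),
                      rep("g", 6))
  ev <- fit3$n.event > 0
  expect_equal(fit3$surv[ev], c(5 / 6, 5 / 8, 5 / 12, 0), tolerance = 1e-12)

  expect_error(km_estimate(surv_df(1, 1, "a"), c(a = NA)), "missing")
})

test_that("log-rank matches the hand-computed O-E/V statistic and null cases", {
  # identical survival experience in both groups
  rec <- surv_df(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0))
  same <- logrank_test(rec, rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1, tolerance = 1e-12)

  # 4 subjects, distinct event times; hand computation gives chi^2 = 8/13
  toy <- logrank_test(surv_df(c(1, 3, 2, 4), c(1, 1, 1, 1)),
                      c("A", "A", "B", "B"))
  expect_equal(toy$statistic, 8 / 13, tolerance = 1e-10)
  expect_equal(toy$df, 1L)
  expect_equal(toy$p.value, pchisq(8 / 13, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_error(logrank_test(rec, rep("a", 6)), ">= 2 groups")
})

test_that("log-rank is invariant to group relabeling and monotone time maps", {
  rec <- surv_df(c(2, 5, 7, 9, 3, 6, 11, 4), c(1, 1, 0, 1, 1, 0, 1, 1))
  grp <- rep(c("x", "y"), 4)
  a <- logrank_test(rec, grp)
  b <- logrank_test(rec, ifelse(grp == "x", "y", "x"))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  rec2 <- rec
  rec2$time <- rec$time^2  # strictly monotone transform
  expect_equal(logrank_test(rec2, grp)$statistic, a$statistic,
               tolerance = 1e-12)
})

test_that("the poorest-prognosis group minimizes restricted mean survival", {
  rec <- surv_df(c(1, 1, 1, 10, 10, 10), c(1, 1, 1, 0, 0, 0))
  expect_equal(identify_poorest_group(rec, rep(c("A", "B"), each = 3)), "A")
  # symmetric groups tie toward the smallest label
  rec2 <- surv_df(c(1, 2, 1, 2), c(1, 1, 1, 1))
  expect_equal(identify_poorest_group(rec2, c("g2", "g2", "g1", "g1")), "g1")
  # high-hazard group found in simulation
  hits <- 0L
  for (seed in 1:10) {
    co <- withr::with_seed(seed, {
      n <- 100
      grp <- rep(1:3, each = n)
      haz <- c(0.1, 0.5, 1.0)[grp]
      surv_df(rexp(3 * n, haz), rep(1, 3 * n))
    })
    if (identify_poorest_group(co, rep(1:3, each = 100)) == "3")
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("correlation-to-reference classification follows r > threshold", {
  ref <- setNames(c(2, -1, 0.5, 1, -2), paste0("G", 1:5))
  model <- list(reference_profile = ref, threshold = 0.3)
  m <- cbind(p1 = ref, p2 = -ref, p3 = ref + rnorm(5, sd = 0.1))
  lab <- classify_by_correlation(m, model)
  expect_equal(unname(lab[c("p1", "p2")]), c("poor", "good"))
  expect_equal(unname(attr(lab, "r")["p1"]), 1, tolerance = 1e-12)

  # raising the threshold can only shrink the poor set
  rmat <- cbind(p1 = ref, p2 = ref + rnorm(5), p3 = rnorm(5), p4 = -ref)
  prev <- Inf
  for (thr in seq(-0.9, 0.9, 0.3)) {
    n_poor <- sum(classify_by_correlation(
      rmat, list(reference_profile = ref, threshold = thr)) == "poor")
    expect_lte(n_poor, prev)
    prev <- n_poor
  }
  expect_error(classify_by_correlation(m[1:2, ], model), "fewer than 3")
})

test_that("threshold selection is deterministic and handles the degenerate grid", {
  sim <- simulate_cohort(n_patients = 60, genes = sprintf("G%03d", 1:30),
                         signature_genes = sprintf("G%03d", 1:10),
                         hazard_ratio = 4, seed = 2)
  thr1 <- cv_select_threshold(sim$cohort, sprintf("G%03d", 1:10),
                              repeats = 3, seed = 11)
  thr2 <- cv_select_threshold(sim$cohort, sprintf("G%03d", 1:10),
                              repeats = 3, seed = 11)
  expect_identical(as.numeric(thr1), as.numeric(thr2))
  expect_true(thr1 >= -1 && thr1 <= 1)

  thrd <- cv_select_threshold(sim$cohort, sprintf("G%03d", 1:10),
                              grid = -1, repeats = 2, seed = 1)
  expect_equal(as.numeric(thrd), -1)
  lab <- classify_by_correlation(sim$cohort,
                                 list(reference_profile = setNames(rnorm(10), sprintf("G%03d", 1:10)),
                                      threshold = -1))
  expect_true(all(lab == "poor" | is.na(attr(lab, "r"))))
})

test_that("the trained model separates survival on a planted-signature cohort", {
  genes <- sprintf("G%03d", 1:40)
  sig <- genes[1:15]
  train <- simulate_cohort(n_patients = 150, genes = genes,
                           signature_genes = sig, hazard_ratio = 4, seed = 31)
  test <- simulate_cohort(n_patients = 150, genes = genes,
                          signature_genes = sig, hazard_ratio = 4, seed = 32)
  model <- train_prognostic_model(train$cohort, sig, repeats = 10, seed = 33)
  lab <- classify_by_correlation(test$cohort, model)
  ev <- evaluate_prognosis(test$cohort, lab)
  expect_lt(ev$logrank$p.value, 0.05)
  # the reference profile should resemble the planted template
  expect_gt(cor(model$reference_profile[sig], test$truth$template[sig]), 0.8)
  expect_error(evaluate_prognosis(test$cohort,
                                  setNames(rep("poor", 150),
                                           test$cohort$survival$sample)),
               ">= 2 groups")
})

test_that("covariate-style labels plug into the same log-rank comparison", {
  sim <- simulate_cohort(n_patients = 80, genes = sprintf("G%03d", 1:10),
                         signature_genes = sprintf("G%03d", 1:5),
                         hazard_ratio = 3, seed = 44)
  mut <- ifelse(sim$truth$poor, "mutant", "wildtype")  # covariate tracking risk
  ev <- evaluate_prognosis(sim$cohort, mut)
  expect_lt(ev$logrank$p.value, 0.05)
})
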