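test_that("feature assembly produces the documented columns and units", {
  tbl <- signal_feature_cohort(n = 12)
  fa <- build_features(tbl, "model", unit = "visit")
  expect_equal(attr(fa, "features"), c("U", "K", "phi", "pf"))
  expect_equal(ncol(fa), 2 + 4)  # subject_id, label + 4 features
  fb <- build_features(tbl[1:3, ], "markers", unit = "visit")
  expect_equal(nrow(fb), 3)
  expect_equal(attr(fb, "features"), c("tau", "ptau", "abeta"))
  # subject-level reduction averages visits
  two_visits <- dplyr::bind_rows(
    dplyr::mutate(tbl, month = 12),
    dplyr::mutate(tbl, month = 24, U = U + 1))
  fs <- build_features(two_visits, "model", unit = "subject")
  expect_equal(nrow(fs), nrow(tbl))
  expect_equal(fs$U[order(fs$subject_id)],
               (tbl$U + tbl$U + 1)[order(tbl$subject_id)] / 2)
  expect_error(build_features(dplyr::select(tbl, -U), "model"),
               class = "minibalance_assembly_error")
})

test_that("well-separated clusters classify perfectly; folds are deterministic", {
  tbl <- signal_feature_cohort(n = 20, signal_cols = c("U", "K", "phi", "pf"),
                               sep = 30)
  fa <- build_features(tbl, "model", unit = "visit")
  rep1 <- crossvalidate(fa, task = "AD", seed = 1)
  expect_equal(rep1$accuracy, 100)
  expect_equal(rep1$sensitivity, 100)
  expect_equal(rep1$specificity, 100)
  # same seed, same folds, same report
  rep2 <- crossvalidate(fa, task = "AD", seed = 1)
  expect_identical(rep1$fold_assignment, rep2$fold_assignment)
  expect_identical(tidy(rep1), tidy(rep2))
  # metrics recompute from the pooled confusion matrix
  cm <- rep1$confusion
  expect_equal(rep1$accuracy, 100 * sum(diag(cm)) / sum(cm))
  expect_equal(rep1$sensitivity, 100 * cm["AD", "AD"] / sum(cm["AD", ]))
  expect_equal(rep1$specificity,
               100 * cm["Normal", "Normal"] / sum(cm["Normal", ]))
  # duplicating every record leaves pooled metrics unchanged
  dup <- dplyr::mutate(dplyr::bind_rows(fa, fa),
                       subject_id = make.unique(subject_id))
  attr(dup, "features") <- attr(fa, "features")
  class(dup) <- class(fa)
  expect_equal(crossvalidate(dup, task = "AD", seed = 1)$accuracy, 100)
  # a class smaller than the fold count is refused by name
  expect_error(crossvalidate(fa[c(1:5, 21:40), ], task = "AD", folds = 10),
               class = "minibalance_stratification_error")
})

test_that("permuted labels collapse accuracy to chance", {
  tbl <- signal_feature_cohort(n = 100, signal_cols = "U", sep = 6, seed = 8)
  accs <- vapply(1:5, function(s) {
    set.seed(s)
    perm <- tbl
    perm$group <- sample(perm$group)
    crossvalidate(build_features(perm, "model", unit = "visit"),
                  task = "AD", seed = s)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 10)
})

test_that("feature-set comparison covers the ablations and ranks U first", {
  tbl <- signal_feature_cohort(n = 30, signal_cols = "U", sep = 5, seed = 9)
  cmp <- compare_feature_sets(tbl, task = "AD", folds = 10, seed = 2,
                              unit = "visit")
  expect_setequal(cmp$feature_set,
                  c("model", "markers", "K+phi", "K+U", "phi+U"))
  acc <- setNames(cmp$accuracy, cmp$feature_set)
  # only U carries signal: the ablation dropping U hurts the most
  expect_lt(acc[["K+phi"]], acc[["K+U"]])
  expect_lt(acc[["K+phi"]], acc[["phi+U"]])
  expect_gt(acc[["model"]], acc[["markers"]])
})

test_that("least-squares pf-MMSE regression recovers exact and null signals", {
  mmse <- rep(10:30, 4)
  exact <- tibble::tibble(pf = 0.9 - 0.02 * mmse, mmse = mmse)
  fit <- suppressWarnings(regress_pf_vs_mmse(exact))  # exact fit warns in lm
  expect_equal(fit$slope, -0.02, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.9, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # reciprocal predictor variant
  inv <- tibble::tibble(pf = 0.1 + 2 / mmse, mmse = mmse)
  fit_inv <- suppressWarnings(regress_pf_vs_mmse(inv, predictor = "inv_mmse"))
  expect_equal(fit_inv$slope, 2, tolerance = 1e-10)
  expect_equal(fit_inv$r_squared, 1, tolerance = 1e-10)
  # independence null: R^2 near zero
  set.seed(10)
  null <- tibble::tibble(pf = runif(1000), mmse = sample(10:30, 1000, TRUE))
  expect_lt(regress_pf_vs_mmse(null)$r_squared, 0.01)
  expect_error(regress_pf_vs_mmse(tibble::tibble(pf = c(.1, .2, .3),
                                                 mmse = c(25, 25, 25))),
               class = "minibalance_regression_error")
})

test_that("longitudinal summaries aggregate group-by-month cells", {
  fix <- tibble::tibble(
    group = factor(rep(c("Normal", "AD"), each = 3),
                   levels = c("Normal", "MCI", "AD")),
    month = rep(c(12, 12, 24), 2),
    U = c(1, 3, 5, 10, 20, 40),
    K = 1, phi = 0)
  s <- longitudinal_summary(fix)
  expect_equal(nrow(s), 4)
  expect_equal(s$U_mean[s$group == "Normal" & s$month == 12], 2)
  expect_equal(s$U_mean[s$group == "AD" & s$month == 12], 15)
  expect_equal(s$U_sd[s$group == "AD" & s$month == 24], 0)  # single record
  # full design: 3 groups x 4 months
  cohort <- generate_cohort(cohort_config(
    group_sizes = c(Normal = 8, MCI = 8, AD = 8), seed = 2))
  p <- cohort_disruption(cohort, reference_state(cohort))
  expect_equal(nrow(longitudinal_summary(p)), 12)
})

test_that("disruption parameters separate the groups (one-way ANOVA)", {
  cohort <- generate_cohort(cohort_config(
    group_sizes = c(Normal = 60, MCI = 60, AD = 30), seed = 14))
  p <- cohort_disruption(cohort, reference_state(cohort))
  for (v in c("U", "K", "phi")) {
    pval <- summary(aov(p[[v]] ~ p$group))[[1]][["Pr(>F)"]][1]
    expect_lt(pval, 0.01)
  }
  # direction: disease groups sit above Normal in U
  m <- tapply(p$U, p$group, mean)
  expect_gt(m[["MCI"]], m[["Normal"]])
  expect_gt(m[["AD"]], m[["MCI"]])
})
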