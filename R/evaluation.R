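#' Assemble a feature table for classification
#'
#' Two feature sets are compared: the model-derived set (`"model"`: U, K,
#' phi and the disruption probability pf) and the raw CSF marker set
#' (`"markers"`: tau, ptau, abeta).  Ablation sets dropping one disruption
#' parameter (`"K+phi"`, `"K+U"`, `"phi+U"`, each plus pf) quantify the
#' dropped parameter's contribution.  With `unit = "subject"` (default) the
#' per-visit rows are reduced to one row per subject by the `reduce`
#' function; `unit = "visit"` keeps one row per subject-visit.
#'
#' Features are returned unstandardized; [crossvalidate()] standardizes
#' within each fold using training-fold statistics only.
#'
#' @param data Cohort tibble carrying `U`, `K`, `phi` (from
#'   [cohort_disruption()]) and, for model-based sets, a `pf` column.
#' @param feature_set One of `"model"`, `"markers"`, `"K+phi"`, `"K+U"`,
#'   `"phi+U"`.
#' @param unit `"subject"` or `"visit"`.
#' @param reduce Function reducing a subject's visit values to one number.
#' @return Tibble with `subject_id`, `label` (the diagnostic group) and one
#'   column per feature; class `feature_table` with the feature names in
#'   `attr(, "features")`.
#' @export
build_features <- function(data,
                           feature_set = c("model", "markers",
                                           "K+phi", "K+U", "phi+U"),
                           unit = c("subject", "visit"),
                           reduce = mean) {
  feature_set <- match.arg(feature_set)
  unit <- match.arg(unit)
  features <- switch(feature_set,
    "model" = c("U", "K", "phi", "pf"),
    "markers" = c("tau", "ptau", "abeta"),
    "K+phi" = c("K", "phi", "pf"),
    "K+U" = c("K", "U", "pf"),
    "phi+U" = c("phi", "U", "pf")
  )
  missing_cols <- setdiff(c("subject_id", "group", features), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("feature assembly needs columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "minibalance_assembly_error")
  }
  if (anyNA(data[, features])) {
    abort("feature columns contain missing values",
          class = "minibalance_assembly_error")
  }
  tbl <- if (unit == "subject") {
    data |>
      dplyr::group_by(.data$subject_id, label = .data$group) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(features), reduce),
                       .groups = "drop")
  } else {
    dplyr::select(data, "subject_id", label = "group",
                  dplyr::all_of(features))
  }
  structure(tbl, features = features, class = c("feature_table", class(tbl)))
}

# stratified fold assignment: shuffles within class, deals folds round-robin
stratified_folds <- function(labels, folds) {
  assignment <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

#' Cross-validated SVM classification
#'
#' Stratified k-fold cross-validation of a support vector machine (RBF
#' kernel, default hyperparameters) separating a disease group from the
#' Normal group.  Features are standardized per fold with training-fold mean
#' and standard deviation; fold predictions are pooled into one confusion
#' matrix from which accuracy, sensitivity (disease class positive) and
#' specificity are computed as percentages.
#'
#' @param table A [build_features()] table.
#' @param task `"AD"` or `"MCI"`: the disease class contrasted with Normal.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param kernel,cost SVM settings passed to [e1071::svm()].
#' @param fold_assignment Optional precomputed integer fold vector (aligned
#'   with the rows of the task subset) so several feature sets can share
#'   identical folds; overrides `seed`.
#' @return An object of class `classification_report`.
#' @export
crossvalidate <- function(table, task = c("AD", "MCI"), folds = 10,
                          seed = 1L, kernel = "radial", cost = 1,
                          fold_assignment = NULL) {
  task <- match.arg(task)
  features <- attr(table, "features")
  sub <- dplyr::filter(table, .data$label %in% c(task, "Normal"))
  sub$label <- droplevels(factor(sub$label, levels = c("Normal", task)))
  counts <- base::table(sub$label)
  if (any(counts < folds)) {
    short <- names(counts)[counts < folds][1]
    abort(sprintf("class %s has %d member(s): fewer than %d folds",
                  short, counts[[short]], folds),
          class = "minibalance_stratification_error")
  }

  if (is.null(fold_assignment)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(as.integer(seed))
    fold_assignment <- stratified_folds(as.character(sub$label), folds)
  }
  stopifnot(length(fold_assignment) == nrow(sub))

  x <- as.matrix(sub[, features])
  truth <- sub$label
  pred <- factor(rep(NA_character_, nrow(sub)), levels = levels(truth))
  for (k in seq_len(folds)) {
    test_idx <- which(fold_assignment == k)
    train_idx <- setdiff(seq_len(nrow(sub)), test_idx)
    mu <- colMeans(x[train_idx, , drop = FALSE])
    sg <- apply(x[train_idx, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    xtr <- scale(x[train_idx, , drop = FALSE], center = mu, scale = sg)
    xte <- scale(x[test_idx, , drop = FALSE], center = mu, scale = sg)
    fit <- e1071::svm(x = xtr, y = truth[train_idx], kernel = kernel,
                      cost = cost, scale = FALSE)
    pred[test_idx] <- predict(fit, xte)
  }

  cm <- base::table(truth = truth, pred = pred)
  tp <- cm[task, task]; tn <- cm["Normal", "Normal"]
  fn <- cm[task, "Normal"]; fp <- cm["Normal", task]
  structure(
    list(task = paste(task, "vs Normal"),
         accuracy = 100 * (tp + tn) / sum(cm),
         sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (tn + fp),
         confusion = cm, folds = folds, seed = as.integer(seed),
         fold_assignment = fold_assignment, n = nrow(sub)),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s (n = %d, %d-fold CV)\n",
              x$task, x$n, x$folds))
  cat(sprintf("  accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
tidy.classification_report <- function(x, ...) {
  tibble::tibble(task = x$task, accuracy = x$accuracy,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 folds = x$folds, n = x$n)
}

#' @export
glance.classification_report <- function(x, ...) tidy.classification_report(x)

#' Compare model-derived and raw-marker feature sets
#'
#' Runs [crossvalidate()] for the model feature set (U, K, phi, pf), the raw
#' CSF marker set, and the three leave-one-parameter-out ablations, with
#' identical fold assignments across feature sets so differences reflect the
#' features alone.
#'
#' @param data Cohort tibble with disruption parameters and `pf`.
#' @param task `"AD"` or `"MCI"`.
#' @param folds,seed,unit See [crossvalidate()] and [build_features()].
#' @return Tibble of one [tidy()] row per feature set, with `feature_set`.
#' @export
compare_feature_sets <- function(data, task = c("AD", "MCI"), folds = 10,
                                 seed = 1L, unit = "subject") {
  task <- match.arg(task)
  sets <- c("model", "markers", "K+phi", "K+U", "phi+U")
  first <- crossvalidate(build_features(data, "model", unit = unit),
                         task = task, folds = folds, seed = seed)
  shared_folds <- first$fold_assignment
  purrr::map_dfr(sets, function(fs) {
    rep <- if (fs == "model") first else
      crossvalidate(build_features(data, fs, unit = unit), task = task,
                    folds = folds, seed = seed,
                    fold_assignment = shared_folds)
    dplyr::mutate(tidy.classification_report(rep), feature_set = fs,
                  .before = 1)
  })
}

#' Regress disruption probability on MMSE
#'
#' Ordinary least squares of the network disruption probability on the MMSE
#' score (or its reciprocal): disruption probability tracking 1/MMSE is the
#' signature of network imbalance following cognitive decline.
#'
#' @param data Data frame with `pf` and `mmse` columns.
#' @param predictor `"mmse"` or `"inv_mmse"` (1/MMSE).
#' @return An object of class `pf_regression` wrapping the [lm()] fit, with
#'   `slope`, `intercept`, `r_squared`, `predictor`.
#' @export
regress_pf_vs_mmse <- function(data, predictor = c("mmse", "inv_mmse")) {
  predictor <- match.arg(predictor)
  if (nrow(data) < 3) abort("need at least 3 paired observations")
  x <- if (predictor == "mmse") data$mmse else 1 / data$mmse
  if (sd(x) == 0) {
    abort("constant predictor: regression undefined",
          class = "minibalance_regression_error")
  }
  fit <- lm(pf ~ x, data = tibble::tibble(pf = data$pf, x = x))
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared, predictor = predictor,
         n = nrow(data), fit = fit),
    class = "pf_regression"
  )
}

#' @export
print.pf_regression <- function(x, ...) {
  cat(sprintf("<pf_regression> pf ~ %s (n = %d): slope %.4g, intercept %.4g, R^2 %.3f\n",
              x$predictor, x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
tidy.pf_regression <- function(x, ...) {
  tibble::tibble(predictor = x$predictor, slope = x$slope,
                 intercept = x$intercept, r_squared = x$r_squared, n = x$n)
}

#' @export
glance.pf_regression <- function(x, ...) tidy.pf_regression(x)

#' Group-by-month trajectory summaries
#'
#' Mean and standard deviation of the disruption probability and parameters
#' per diagnostic group per visit month — the numbers behind trajectory and
#' boxplot figures.
#'
#' @param data Cohort tibble with `U`, `K`, `phi` and optionally `pf`.
#' @return Tibble with one row per group x month and `<var>_mean`,
#'   `<var>_sd` columns; cells with a single record get sd 0.  Group-month
#'   cells absent from the data are absent from the output, not fabricated.
#' @export
longitudinal_summary <- function(data) {
  vars <- intersect(c("pf", "U", "K", "phi"), names(data))
  data |>
    dplyr::group_by(.data$group, .data$month) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(vars),
                    list(mean = mean,
                         sd = ~ if (length(.x) < 2) 0 else sd(.x))),
      .groups = "drop"
    )
}
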