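#' Pipeline configuration
#'
#' Bundles the settings of every stage: cohort generation, the normalized
#' network model, the perturbation and Monte Carlo settings, and evaluation.
#' `read_pipeline_config()` reads the same structure from a YAML file whose
#' top-level keys mirror the arguments below; list-valued YAML entries are
#' merged into the defaults.
#'
#' @param cohort A [cohort_config()], or `NULL` with `cohort_csv` to analyse
#'   an existing cohort file.
#' @param cohort_csv Optional path to a cohort CSV read with [read_cohort()].
#' @param network List: `n_compartments`, `tau`, and `clearance` for the
#'   normalized-scale [build_network()] model.
#' @param perturbation List: `sigma` (lognormal sigma) and `targets`.
#' @param monte_carlo An [mc_config()].
#' @param mode `"static"` or `"coupled"` formation of the pathological
#'   vector.
#' @param horizon Propagation horizon, months (coupled mode).
#' @param rule Disruption rule (see [is_disrupted()]).
#' @param evaluation List: `enabled`, `folds`, `unit`, `tasks`.
#' @param seed Global seed; stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            cohort_csv = NULL,
                            network = list(n_compartments = 3, tau = 0.5,
                                           clearance = c(abeta = 1, tau = 1,
                                                         ptau = 1)),
                            perturbation = list(sigma = 0.25,
                                                targets = marker_names()),
                            monte_carlo = mc_config(max_iterations = 2e4),
                            mode = c("static", "coupled"),
                            horizon = 1,
                            rule = c("any", "all"),
                            evaluation = list(enabled = TRUE, folds = 10,
                                              unit = "subject",
                                              tasks = c("AD", "MCI")),
                            seed = 1L) {
  structure(
    list(cohort = cohort, cohort_csv = cohort_csv, network = network,
         perturbation = perturbation, monte_carlo = monte_carlo,
         mode = match.arg(mode), horizon = horizon, rule = match.arg(rule),
         evaluation = evaluation, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  args <- list()
  if (!is.null(y$cohort)) {
    ca <- y$cohort
    for (nm in c("group_sizes", "marker_means_normal", "male_frac")) {
      if (!is.null(ca[[nm]])) ca[[nm]] <- unlist(ca[[nm]])
    }
    for (nm in c("group_effect_multipliers", "longitudinal_drift")) {
      if (!is.null(ca[[nm]])) ca[[nm]] <- lapply(ca[[nm]], unlist)
    }
    if (!is.null(ca$mmse_params)) {
      ca$mmse_params <- modifyList(formals(cohort_config)$mmse_params |> eval(),
                                   lapply(ca$mmse_params, unlist))
    }
    args$cohort <- do.call(cohort_config, ca)
  }
  if (!is.null(y$monte_carlo)) args$monte_carlo <- do.call(mc_config, y$monte_carlo)
  for (nm in c("cohort_csv", "mode", "horizon", "rule", "seed")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  for (nm in c("network", "perturbation", "evaluation")) {
    if (!is.null(y[[nm]])) {
      merged <- modifyList(defaults[[nm]], y[[nm]])
      if (!is.null(merged$clearance)) merged$clearance <- unlist(merged$clearance)
      if (!is.null(merged$targets)) merged$targets <- unlist(merged$targets)
      if (!is.null(merged$tasks)) merged$tasks <- unlist(merged$tasks)
      args[[nm]] <- merged
    }
  }
  do.call(pipeline_config, args)
}

#' Run the full network-balance pipeline
#'
#' Executes every stage on one configuration: cohort generation (or CSV
#' read), normal-state reference estimation, per-record disruption
#' parameters, Normal-group threshold calibration, per-record Monte Carlo
#' disruption probability, marker-contribution analysis on the AD group
#' mean state, and (optionally) the MMSE regression and SVM comparisons.
#' Every numeric output is re-derivable from (config, seed) alone.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, each stage's table is
#'   written as CSV (full double precision) and a `manifest.json` records
#'   the configuration hash, seed, stage outputs, the exclusion count and
#'   the final iteration counts.
#' @return List with `cohort`, `reference`, `params` (cohort with U/K/phi
#'   and pf columns), `thresholds`, `contributions`, `regression`,
#'   `classification`, `summary`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  cohort <- if (!is.null(config$cohort_csv)) read_cohort(config$cohort_csv)
    else generate_cohort(validate_cohort_config(
      modifyList(unclass(config$cohort), list(seed = seed))))
  n_excluded <- attr(cohort, "n_excluded") %||% 0L

  reference <- reference_state(cohort)
  params <- cohort_disruption(cohort, reference)
  thresholds <- calibrate_thresholds(
    dplyr::filter(params, .data$group == "Normal"))

  model <- if (config$mode == "coupled") {
    build_network(c(abeta = 1, tau = 1, ptau = 1),
                  clearance = as_marker_vector(config$network$clearance),
                  chains = default_chains(config$network$n_compartments,
                                          config$network$tau))
  } else NULL

  spec <- perturbation_spec(config$perturbation$targets,
                            config$perturbation$sigma)
  mc_runs <- purrr::map(seq_len(nrow(params)), function(i) {
    estimate_disruption_probability(
      as_marker_vector(params[i, ]), reference, thresholds, spec = spec,
      mc = config$monte_carlo, mode = config$mode, model = model,
      horizon = config$horizon, rule = config$rule,
      seed = (seed + i) %% .Machine$integer.max
    )
  })
  params$pf <- vapply(mc_runs, `[[`, numeric(1), "pf")
  params$mc_D <- vapply(mc_runs, `[[`, integer(1), "D")
  params$mc_converged <- vapply(mc_runs, `[[`, logical(1), "converged")

  ad <- dplyr::filter(cohort, .data$group == "AD")
  contributions <- if (nrow(ad) > 0) {
    ad_state <- vapply(ad[, marker_names()], mean, numeric(1))
    marker_contributions(
      ad_state, reference, thresholds,
      subsets = list("abeta", "tau", "ptau", c("abeta", "ptau"),
                     c("tau", "ptau"), c("abeta", "tau")),
      sigma = config$perturbation$sigma, mc = config$monte_carlo,
      mode = config$mode, model = model, horizon = config$horizon,
      rule = config$rule, seed = seed + nrow(params) + 1L
    )
  } else NULL

  regression <- NULL
  classification <- NULL
  if (isTRUE(config$evaluation$enabled)) {
    regression <- regress_pf_vs_mmse(params)
    classification <- purrr::map_dfr(config$evaluation$tasks, function(tk) {
      n_by_group <- base::table(
        dplyr::distinct(params, .data$subject_id, .data$group)$group)
      if (any(n_by_group[c("Normal", tk)] < config$evaluation$folds)) {
        return(NULL)
      }
      compare_feature_sets(params, task = tk,
                           folds = config$evaluation$folds, seed = seed,
                           unit = config$evaluation$unit)
    })
  }
  summary_tbl <- longitudinal_summary(params)

  manifest <- list(
    config_hash = rlang::hash(config), seed = seed,
    n_records = nrow(params), n_excluded = n_excluded,
    mc_iterations = range(params$mc_D),
    stages = c("cohort", "reference", "params", "thresholds", "pf",
               "contributions",
               if (isTRUE(config$evaluation$enabled)) "evaluation"),
    outputs = character(0)
  )

  result <- list(cohort = cohort, reference = reference, params = params,
                 thresholds = thresholds, contributions = contributions,
                 regression = regression, classification = classification,
                 summary = summary_tbl, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(tbl, name) {
      if (is.null(tbl)) return(NULL)
      p <- file.path(out_dir, paste0(name, ".csv"))
      readr::write_csv(tbl, p)
      p
    }
    outputs <- c(
      wr(params, "params"),
      wr(contributions, "contributions"),
      wr(if (!is.null(regression)) tidy.pf_regression(regression), "regression"),
      wr(classification, "classification"),
      wr(summary_tbl, "longitudinal_summary"),
      wr(tibble::tibble(marker = marker_names(), reference = unname(reference)),
         "reference")
    )
    result$manifest$outputs <- basename(outputs)
    jsonlite::write_json(result$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
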