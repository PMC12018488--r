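## orchestration: config-driven end-to-end pipeline
## (simulate/ingest -> impute -> estimate -> calibrate -> recode -> discover
##  -> effects -> report), with artifact writing and reproducibility capture.

#' Build / validate a pipeline configuration
#'
#' Exactly one of `data` (CSV path, with its schema sidecar) or `simulation`
#' (a [sim_config()] or list of its arguments) must be given, and exactly one
#' of `estimator` (settings for [fit_cate_model()]) or `external_cate` (CSV of
#' imported estimates). Defaults: `max_depth` 2, `min_leaf` 50, `n_boot` 200,
#' level 0.95, propensity = the known randomization share (0.5 or the
#' simulation's), 99th-percentile weight truncation, Qini on the counts scale.
#'
#' @param data Path to a trial CSV written by [write_dataset()], or `NULL`.
#' @param simulation A [sim_config()] or argument list, or `NULL`.
#' @param estimator List of [fit_cate_model()] settings, or `NULL`.
#' @param external_cate Path to imported CATE estimates, or `NULL`.
#' @param rules Path to a recoding YAML; `NULL` uses the shipped default.
#' @param impute Impute missing covariates by median/mode first (default TRUE).
#' @param max_depth,min_leaf [fit_tree()] settings.
#' @param n_boot,level [c_for_benefit()] settings.
#' @param qini_scale `"counts"` or `"per-subject"`.
#' @param propensity Known randomization probability; `NULL` = 0.5 or the
#'   simulation's `treatment_probability`.
#' @param truncation_quantile IPCW weight-truncation quantile.
#' @param seed Master seed; stage seeds are derived from it deterministically.
#' @param out_dir Directory for artifacts.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(data = NULL, simulation = NULL,
                            estimator = list(), external_cate = NULL,
                            rules = NULL, impute = TRUE,
                            max_depth = 2, min_leaf = 50,
                            n_boot = 200, level = 0.95,
                            qini_scale = "counts",
                            propensity = NULL,
                            truncation_quantile = 0.99,
                            seed = 1L, out_dir = tempfile("pragsub_run_")) {
  if (is.null(data) == is.null(simulation)) {
    stop_ps("exactly one of 'data' (path) or 'simulation' (config) is required",
            class = "pragsub_config_error")
  }
  if (!is.null(external_cate) && length(estimator) > 0) {
    stop_ps("give either 'estimator' settings or an 'external_cate' path, not both",
            class = "pragsub_config_error")
  }
  if (!is.null(simulation) && !inherits(simulation, "sim_config")) {
    simulation <- do.call(sim_config, simulation)
  }
  assert_that(qini_scale %in% c("counts", "per-subject"),
              "qini_scale must be 'counts' or 'per-subject'",
              class = "pragsub_config_error")
  if (is.null(propensity)) {
    propensity <- if (!is.null(simulation)) simulation$treatment_probability else 0.5
  }
  structure(list(data = data, simulation = simulation,
                 estimator = estimator, external_cate = external_cate,
                 rules = rules, impute = isTRUE(impute),
                 max_depth = max_depth, min_leaf = min_leaf,
                 n_boot = n_boot, level = level, qini_scale = qini_scale,
                 propensity = propensity,
                 truncation_quantile = truncation_quantile,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Field names mirror the [pipeline_config()] arguments; `simulation` is the
#' argument list of [sim_config()]. Missing fields take the documented
#' defaults; invalid combinations are rejected with messages naming the
#' offending fields.
#'
#' @param path YAML file path.
#' @param out_dir,seed Optional overrides of the file's values.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path, out_dir = NULL, seed = NULL) {
  assert_that(file.exists(path), "no such config file: ", path,
              class = "pragsub_io_error")
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  assert_that(length(unknown) == 0, "unknown config field(s): ",
              paste(unknown, collapse = ", "), class = "pragsub_config_error")
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  if (!is.null(seed)) raw$seed <- seed
  do.call(pipeline_config, raw)
}

#' Serialize a pipeline configuration to YAML
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  assert_that(inherits(config, "pipeline_config"), "not a pipeline_config")
  x <- unclass(config)
  if (!is.null(x$simulation)) {
    sim <- unclass(x$simulation)
    sim$roster <- NULL
    sim$cell_effects <- as.list(sim$cell_effects)
    sim$censoring_coefficients <- as.list(sim$censoring_coefficients)
    x$simulation <- sim
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Median / mode imputation of covariates
#'
#' Continuous covariates are imputed by the column median of observed values,
#' binary and categorical ones by the mode (ties broken by level order).
#' `treatment`, `outcome` and `retained` are never imputed: missingness there
#' is a contract violation, not a data gap. A per-column imputed-count report
#' is attached as `attr(, "imputation")`.
#'
#' @param dataset A `trial_data`.
#' @return The imputed `trial_data`.
#' @export
impute_simple <- function(dataset) {
  assert_that(inherits(dataset, "trial_data"), "dataset must be a trial_data")
  assert_that(!anyNA(dataset$treatment) && !anyNA(dataset$retained),
              "treatment/retained contain missing values; these are never imputed")
  assert_that(!anyNA(dataset$outcome[dataset$retained == 1L]),
              "outcome missing for retained subjects; outcomes are never imputed")
  kinds <- attr(dataset, "kinds")
  counts <- integer(0)
  for (nm in names(kinds)) {
    x <- dataset[[nm]]
    miss <- is.na(x)
    counts[nm] <- sum(miss)
    if (!any(miss)) next
    if (all(miss)) stop_ps("covariate '", nm, "' is entirely missing")
    if (kinds[[nm]] == "continuous") {
      x[miss] <- median(x[!miss])
    } else {
      tab <- table(x[!miss])
      x[miss] <- if (is.factor(x)) factor(names(tab)[which.max(tab)],
                                          levels = levels(x))
                 else if (kinds[[nm]] == "binary") as.integer(names(tab)[which.max(tab)])
                 else names(tab)[which.max(tab)]
    }
    dataset[[nm]] <- x
  }
  attr(dataset, "imputation") <- counts
  dataset
}

#' Run the full two-step pipeline
#'
#' Executes simulate/ingest -> impute -> censoring weights -> CATE estimation
#' (or import) -> calibration -> recoding -> subgroup discovery -> AIPW group
#' effects, writing every intermediate artifact under `config$out_dir`:
#' `data.csv` (+ schema), `cate.csv`, `calib.json`, `qini_curve.csv`,
#' `recoded.csv`, `tree.json`, `rules.txt`, `effects.csv` and `report.json`
#' (which embeds the config hash, stage seeds and package version; timestamps
#' are excluded from the hash). Rerunning with the same config and seed
#' reproduces the outputs.
#'
#' @param config A `pipeline_config`.
#' @return A `report_bundle` (invisibly the same content as `report.json`).
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_add <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_add("FAILED at stage '", name, "': ", conditionMessage(e))
      writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
      stop_ps("pipeline stage '", name, "' failed: ", conditionMessage(e),
              class = "pragsub_stage_error")
    })
  }
  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL
  if (!is.null(cfg_for_hash$simulation)) {
    cfg_for_hash$simulation <- unclass(cfg_for_hash$simulation)
    cfg_for_hash$simulation$roster <- NULL
  }
  hash <- config_hash(cfg_for_hash)
  log_add("config hash ", hash, "; master seed ", config$seed)

  dataset <- stage("ingest", {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      sim$seed <- derive_seed(config$seed, "simulate")
      d <- simulate_trial(sim)
      write_dataset(d, file.path(config$out_dir, "data.csv"))
      d
    } else {
      read_dataset(config$data)
    }
  })
  log_add("ingest: ", nrow(dataset), " subjects, ", sum(dataset$retained),
          " retained")

  if (config$impute) dataset <- stage("impute", impute_simple(dataset))

  weights <- stage("censoring", fit_censoring_weights(
    dataset, truncation_quantile = config$truncation_quantile))
  log_add("censoring: ", weights$metadata$model, " model, cap ",
          signif(weights$metadata$truncation_cap, 4))

  estimate <- stage("estimate", {
    if (!is.null(config$external_cate)) {
      read_cate_estimates(config$external_cate)
    } else {
      est_args <- config$estimator
      est_args$dataset <- dataset
      est_args$weights <- weights
      est_args$seed <- est_args$seed %||% derive_seed(config$seed, "estimate")
      model <- do.call(fit_cate_model, est_args)
      predict_effects(model, dataset)
    }
  })
  write_cate_estimates(estimate, file.path(config$out_dir, "cate.csv"))
  log_add("estimate: ", nrow(estimate), " subjects, provenance ",
          attr(estimate, "provenance")$type)

  calib <- stage("calibrate", {
    qini <- qini_curve(estimate, dataset, weights, scale = config$qini_scale)
    cfb <- c_for_benefit(estimate, dataset, n_boot = config$n_boot,
                         level = config$level,
                         seed = derive_seed(config$seed, "calibrate"))
    write.csv(qini$curve, file.path(config$out_dir, "qini_curve.csv"),
              row.names = FALSE)
    list(qini = qini, cfb = cfb)
  })
  calib_json <- list(
    qini_coefficient = calib$qini$coefficient,
    qini_scale = config$qini_scale,
    c_for_benefit = calib$cfb$statistic,
    c_for_benefit_ci = calib$cfb$ci,
    ci_level = config$level,
    n_boot = config$n_boot,
    n_pairs = calib$cfb$n_pairs
  )
  jsonlite::write_json(calib_json, file.path(config$out_dir, "calib.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  recoded <- stage("recode", {
    rules <- if (is.null(config$rules)) default_rules() else load_rules(config$rules)
    r <- apply_recoding(dataset, rules)
    r[dataset$retained == 1L, , drop = FALSE]
  })
  write.csv(recoded, file.path(config$out_dir, "recoded.csv"), row.names = FALSE)

  tree <- stage("discover", fit_tree(
    estimate, recoded, max_depth = config$max_depth,
    min_leaf = config$min_leaf, weights = weights))
  rules_tab <- rules_text(tree)
  jsonlite::write_json(tree_to_list(tree), file.path(config$out_dir, "tree.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(
    c(sprintf("Discovered subgroups (ascending benefit; n = %d analytic subjects)",
              sum(dataset$retained)),
      sprintf("group %d (n = %d, mean CATE %+.4f): %s",
              rules_tab$group, rules_tab$n, rules_tab$mean_tau, rules_tab$rule)),
    file.path(config$out_dir, "rules.txt"))
  log_add("discover: ", nrow(rules_tab), " subgroups")

  effects <- stage("effects", {
    scores <- aipw_scores(dataset, estimate, propensity = config$propensity,
                          weights = weights)
    groups <- assign_groups(tree, recoded)
    group_ate_table(scores, paste("group", groups), level = config$level)
  })
  write.csv(effects, file.path(config$out_dir, "effects.csv"), row.names = FALSE)

  report <- list(
    provenance = list(config_hash = hash, master_seed = config$seed,
                      package_version = as.character(packageVersion("pragsub")),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    analytic_n = sum(dataset$retained),
    calibration = calib_json,
    rules = rules_tab,
    group_effects = effects
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_add("done; artifacts in ", config$out_dir)
  writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
  structure(report, class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> analytic n = %d (config %s)\n", x$analytic_n,
              x$provenance$config_hash))
  cat(sprintf("  Qini coefficient: %.4f | C-for-benefit: %.4f [%.4f, %.4f]\n",
              x$calibration$qini_coefficient, x$calibration$c_for_benefit,
              x$calibration$c_for_benefit_ci[1], x$calibration$c_for_benefit_ci[2]))
  cat(sprintf("  %d subgroups; group effects (pp):\n", nrow(x$rules)))
  ge <- x$group_effects
  for (i in seq_len(nrow(ge))) {
    cat(sprintf("    %-10s n=%5d  RD %+6.2fpp [%+.2f, %+.2f]\n",
                ge$group[i], ge$n[i], ge$rd_pp[i], ge$ci_lower[i], ge$ci_upper[i]))
  }
  invisible(x)
}
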