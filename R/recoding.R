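## interpretable_recoding: declarative conversion of raw covariates into the
## interpretable covariates used for subgroup discovery. Continuous variables
## are categorized at clinically meaningful cutpoints, some are kept as-is,
## and non-interpretable ones are removed. Intervals are half-open [lo, hi):
## first interval (-Inf, cut_1), last [cut_last, Inf), so the categories
## partition the reals exactly.

#' A single recoding rule
#'
#' @param variable Raw covariate name.
#' @param action `"keep"`, `"categorize"` or `"remove"`.
#' @param cutpoints Strictly increasing numeric boundaries (categorize only).
#' @param labels Ordered category names, `length(cutpoints) + 1` of them
#'   (categorize only); auto-generated from the cutpoints when omitted.
#' @return A `recoding_rule`.
#' @export
recoding_rule <- function(variable, action = c("keep", "categorize", "remove"),
                          cutpoints = NULL, labels = NULL) {
  action <- match.arg(action)
  assert_that(is.character(variable) && length(variable) == 1L && nzchar(variable),
              "variable must be a single name")
  if (action == "categorize") {
    assert_that(is.numeric(cutpoints) && length(cutpoints) >= 1L,
                "rule for '", variable, "': categorize needs numeric cutpoints",
                class = "pragsub_validation_error")
    assert_that(all(diff(cutpoints) > 0),
                "rule for '", variable, "': cutpoints must be strictly increasing",
                class = "pragsub_validation_error")
    if (is.null(labels)) {
      k <- length(cutpoints)
      labels <- c(paste0("< ", cutpoints[1]),
                  if (k > 1) sprintf("%s–%s", cutpoints[-k],
                                     cutpoints[-1]),
                  paste0("≥ ", cutpoints[k]))
    }
    assert_that(length(labels) == length(cutpoints) + 1L,
                "rule for '", variable, "': need ", length(cutpoints) + 1L,
                " labels, got ", length(labels),
                class = "pragsub_validation_error")
    assert_that(!anyDuplicated(labels),
                "rule for '", variable, "': labels must be unique",
                class = "pragsub_validation_error")
  } else {
    assert_that(is.null(cutpoints) && is.null(labels),
                "rule for '", variable, "': ", action,
                " takes no cutpoints or labels",
                class = "pragsub_validation_error")
  }
  structure(list(variable = variable, action = action,
                 cutpoints = cutpoints, labels = labels),
            class = "recoding_rule")
}

#' A set of recoding rules
#'
#' @param rules List of [recoding_rule()]s, at most one per raw covariate.
#' @param unlisted_policy What to do with covariates no rule mentions:
#'   `"keep"` (pass through unchanged, the default) or `"error"`.
#' @return A `recoding_ruleset`.
#' @export
recoding_ruleset <- function(rules = list(), unlisted_policy = c("keep", "error")) {
  unlisted_policy <- match.arg(unlisted_policy)
  assert_that(all(vapply(rules, inherits, TRUE, "recoding_rule")),
              "rules must be recoding_rule objects")
  vars <- vapply(rules, `[[`, "", "variable")
  dup <- vars[duplicated(vars)]
  assert_that(length(dup) == 0,
              "variable(s) appear in more than one rule: ",
              paste(unique(dup), collapse = ", "),
              class = "pragsub_validation_error")
  names(rules) <- vars
  structure(list(rules = rules, unlisted_policy = unlisted_policy),
            class = "recoding_ruleset")
}

#' @export
print.recoding_ruleset <- function(x, ...) {
  acts <- vapply(x$rules, `[[`, "", "action")
  cat(sprintf("<recoding_ruleset> %d rules (%d categorize, %d keep, %d remove); unlisted: %s\n",
              length(x$rules), sum(acts == "categorize"), sum(acts == "keep"),
              sum(acts == "remove"), x$unlisted_policy))
  invisible(x)
}

#' Load a recoding ruleset from YAML
#'
#' The file holds one mapping per variable with fields `action` and, for
#' categorize, `cutpoints` and `labels`, plus an optional top-level
#' `unlisted_policy`. The package ships `table2_lookahead.yaml`, the default
#' clinical ruleset (age at 60; BMI at 18.5/25/30/35/40; HbA1c at
#' 5.7/6.4/7/8/9/10; SBP in 6 groups; SF-36 scales dichotomized at 50; Beck
#' depression in 4 groups; urine albumin/creatinine and the SF-36 transition
#' and component summaries removed; ...), reachable via [default_rules()].
#'
#' @param path YAML file path.
#' @return A [recoding_ruleset()].
#' @export
load_rules <- function(path) {
  assert_that(file.exists(path), "no such rules file: ", path,
              class = "pragsub_io_error")
  raw <- yaml::read_yaml(path)
  policy <- raw$unlisted_policy %||% "keep"
  entries <- raw$rules %||% raw[setdiff(names(raw), "unlisted_policy")]
  rules <- lapply(names(entries), function(nm) {
    e <- entries[[nm]]
    recoding_rule(nm, action = e$action %||% "keep",
                  cutpoints = if (!is.null(e$cutpoints)) as.numeric(e$cutpoints),
                  labels = if (!is.null(e$labels)) as.character(e$labels))
  })
  recoding_ruleset(rules, unlisted_policy = policy)
}

#' The shipped clinical recoding ruleset
#' @return A [recoding_ruleset()] transcribing the default clinical cutpoints.
#' @export
default_rules <- function() {
  load_rules(system.file("extdata", "table2_lookahead.yaml",
                         package = "pragsub", mustWork = TRUE))
}

## Map a numeric vector into the half-open intervals of a categorize rule.
## findInterval with left.open = FALSE gives [cut_k, cut_{k+1}) directly.
cut_halfopen <- function(x, rule) {
  idx <- findInterval(x, rule$cutpoints) + 1L
  factor(rule$labels[idx], levels = rule$labels, ordered = TRUE)
}

#' Apply a recoding ruleset to a trial dataset
#'
#' Produces the interpretable covariate table used for subgroup discovery:
#' categorized columns become ordered factors over the rule's labels, kept
#' columns pass through bitwise unchanged, removed columns are absent.
#' Missing values propagate as missing (imputation happens upstream).
#'
#' @param dataset A `trial_data` (or plain data.frame of covariates).
#' @param rules A [recoding_ruleset()].
#' @return A data.frame with `subject_id` (when available) and the
#'   interpretable covariates; `attr(, "kinds")` declares each output
#'   column's kind.
#' @export
apply_recoding <- function(dataset, rules) {
  assert_that(inherits(rules, "recoding_ruleset"), "rules must be a recoding_ruleset")
  if (inherits(dataset, "trial_data")) {
    kinds <- attr(dataset, "kinds")
    covs <- as.data.frame(dataset)[, names(kinds), drop = FALSE]
    ids <- dataset$subject_id
  } else {
    covs <- as.data.frame(dataset)
    ids <- covs$subject_id
    covs$subject_id <- NULL
    kinds <- vapply(covs, function(x) {
      if (is.factor(x) || is.character(x)) "categorical"
      else if (all(x %in% c(0, 1, NA))) "binary" else "continuous"
    }, "")
  }

  unlisted <- setdiff(names(covs), names(rules$rules))
  if (rules$unlisted_policy == "error" && length(unlisted)) {
    stop_ps("no rule for covariate(s): ", paste(unlisted, collapse = ", "),
            class = "pragsub_validation_error")
  }

  out <- list()
  out_kinds <- character(0)
  for (nm in names(covs)) {
    rule <- rules$rules[[nm]]
    if (is.null(rule) || rule$action == "keep") {
      out[[nm]] <- covs[[nm]]
      out_kinds[nm] <- kinds[[nm]]
    } else if (rule$action == "remove") {
      next
    } else {
      if (kinds[[nm]] != "continuous") {
        stop_ps("categorize rule targets non-continuous covariate '", nm, "'",
                class = "pragsub_type_error")
      }
      out[[nm]] <- cut_halfopen(covs[[nm]], rule)
      out_kinds[nm] <- "categorical"
    }
  }
  res <- as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(ids)) res <- cbind(data.frame(subject_id = ids,
                                             stringsAsFactors = FALSE), res)
  structure(res, kinds = out_kinds)
}

#' Check a ruleset against a dataset without mutating either
#'
#' @param rules A [recoding_ruleset()].
#' @param dataset A `trial_data` or covariate data.frame.
#' @return A `recoding_report`: data.frame with columns `variable`, `issue`
#'   (`missing_variable`, `empty_category`, `removed`), `detail`. An empty
#'   report (possibly minus the informational `removed` rows) means the
#'   ruleset is fully consistent with the data.
#' @export
validate_rules <- function(rules, dataset) {
  assert_that(inherits(rules, "recoding_ruleset"), "rules must be a recoding_ruleset")
  covs <- if (inherits(dataset, "trial_data")) {
    as.data.frame(dataset)[, names(attr(dataset, "kinds")), drop = FALSE]
  } else as.data.frame(dataset)
  rows <- list()
  add <- function(variable, issue, detail) {
    rows[[length(rows) + 1L]] <<- data.frame(variable = variable, issue = issue,
                                             detail = detail,
                                             stringsAsFactors = FALSE)
  }
  for (rule in rules$rules) {
    nm <- rule$variable
    if (!nm %in% names(covs)) {
      add(nm, "missing_variable", "rule references a variable absent from the dataset")
      next
    }
    if (rule$action == "remove") {
      add(nm, "removed", "variable excluded from the interpretable set")
    } else if (rule$action == "categorize" && is.numeric(covs[[nm]])) {
      got <- cut_halfopen(covs[[nm]], rule)
      counts <- table(got)
      for (lab in rule$labels[counts[rule$labels] == 0]) {
        add(nm, "empty_category", paste0("no subject falls in '", lab, "'"))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(0), issue = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  structure(out, class = c("recoding_report", "data.frame"))
}
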