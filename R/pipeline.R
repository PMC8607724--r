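# End-to-end pipeline: cohort (simulated or ingested) -> deliverability
# filtering -> periodic SPC monitoring -> site comparison -> predictor
# screening + n-way ANOVA -> versioned JSON report.

REPORT_SCHEMA_VERSION <- "1.0"

#' Pipeline configuration
#'
#' Defaults match the clinical QA program settings: the four criteria labels
#' 3G2/3L2/3G3/3L3, a 10% low-dose threshold, a deliverability cut of
#' GP%(3%G, 2 mm) > 90, a 40-record baseline, 10,000 bootstrap resamples and
#' six-month monitoring periods.
#'
#' @param cohort a [cohort_spec] to simulate, or NULL when `qa`/`plans` are
#'   supplied directly.
#' @param qa,plans data frames (or CSV paths) of QA records and plan records;
#'   ignored when `cohort` is given.
#' @param criteria criteria labels carried through the report.
#' @param threshold_percent low-dose threshold (documentation field; gamma
#'   results are ingested as GP% here).
#' @param deliverability_cut GP%(3G2) strict lower bound for SPC inclusion.
#' @param baseline_size number of records in the baseline evaluation.
#' @param n_boot bootstrap resamples for the confidence intervals.
#' @param period_boundaries optional explicit boundary dates; by default
#'   six-month periods spanning the observed date range.
#' @param anova_criteria GP% columns analysed by the n-way ANOVA.
#' @param seed integer seed governing every stochastic step.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            qa = NULL, plans = NULL,
                            criteria = c("3G2", "3L2", "3G3", "3L3"),
                            threshold_percent = 10,
                            deliverability_cut = 90,
                            baseline_size = 40,
                            n_boot = 10000,
                            period_boundaries = NULL,
                            anova_criteria = c("gp_3G2", "gp_3L2"),
                            seed = 1L) {
  structure(
    list(cohort = cohort, qa = qa, plans = plans, criteria = criteria,
         threshold_percent = threshold_percent,
         deliverability_cut = deliverability_cut,
         baseline_size = baseline_size, n_boot = n_boot,
         period_boundaries = period_boundaries,
         anova_criteria = anova_criteria, seed = seed),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the [pipeline_config()] arguments; `qa` and `plans`
#' may be CSV paths, and `cohort: default` requests the default simulated
#' cohort.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- NULL
  if (identical(y$cohort, "default")) {
    cohort <- cohort_spec(seed = if (!is.null(y$seed)) y$seed else 1L)
  } else if (is.list(y$cohort)) {
    cohort <- do.call(cohort_spec, y$cohort)
  }
  qa <- if (!is.null(y$qa)) utils::read.csv(y$qa, stringsAsFactors = FALSE)
  plans <- if (!is.null(y$plans)) utils::read.csv(y$plans, stringsAsFactors = FALSE)
  args <- y[intersect(names(y), c("criteria", "threshold_percent",
                                  "deliverability_cut", "baseline_size",
                                  "n_boot", "anova_criteria", "seed"))]
  do.call(pipeline_config, c(list(cohort = cohort, qa = qa, plans = plans), args))
}

#' Six-month monitoring-period boundaries covering a date range
#'
#' The first boundary sits at the first observed date; boundaries advance in
#' calendar six-month steps until the last date is covered.
#'
#' @param dates vector of delivery dates.
#' @return vector of boundary dates (length = number of periods + 1).
#' @export
six_month_boundaries <- function(dates) {
  start <- min(dates)
  b <- start
  while (b[length(b)] <= max(dates)) {
    b <- c(b, seq(b[length(b)], by = "6 months", length.out = 2L)[2L])
  }
  b
}

#' Run the full QA-analysis pipeline
#'
#' Simulates (or ingests) the cohort, applies the deliverability filter,
#' monitors the clinic-specific action and tolerance limits per six-month
#' period, compares GP% across treatment sites (Kruskal-Wallis with
#' Bonferroni post-hoc when significant), screens the planning parameters for
#' mutual correlation and runs the n-way ANOVA per requested criteria
#' column. Stage errors propagate with the stage name attached.
#'
#' @param config a [pipeline_config].
#' @return object of class `qa_report` (a nested list; see
#'   [validate_report()] for its schema).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  if (!is.null(config$cohort)) {
    sim <- stage("simulate", make_plan_cohort(config$cohort))
    plans <- sim$plans
    qa <- sim$qa
  } else {
    if (is.null(config$qa)) stop("pipeline needs either a cohort spec or QA records", call. = FALSE)
    qa <- config$qa
    qa$date <- as.Date(qa$date)
    plans <- config$plans
  }

  deliverable <- stage("filter", filter_deliverable(qa))
  n_excluded <- nrow(qa) - nrow(deliverable)
  message("deliverability filter (GP% 3%G/2 mm > ", config$deliverability_cut,
          "): ", n_excluded, " of ", nrow(qa), " records excluded from SPC")

  boundaries <- config$period_boundaries
  if (is.null(boundaries)) boundaries <- six_month_boundaries(deliverable$date)
  spc <- stage("spc", monitor(deliverable, boundaries, seed = config$seed,
                              n_boot = config$n_boot))

  site_block <- NULL
  if (!is.null(plans)) {
    site_of <- stats::setNames(plans$site, plans$plan_id)
    site_block <- lapply(config$anova_criteria, function(col) {
      groups <- split(qa[[col]], site_of[qa$plan_id])
      groups <- groups[vapply(groups, length, 1L) >= 2L]
      kw <- stage("site-comparison", kruskal_wallis(groups))
      ph <- if (kw$p_value < 0.05) {
        stage("site-comparison", posthoc_bonferroni(groups))
      } else NULL
      list(criteria = col, kruskal_p = kw$p_value, statistic = kw$statistic,
           n_per_site = vapply(groups, length, 1L),
           posthoc_p_adjusted = if (!is.null(ph)) ph$p_adjusted else NULL)
    })
    names(site_block) <- config$anova_criteria
  }

  screening <- NULL
  anova_block <- NULL
  cohort_summary <- NULL
  if (!is.null(plans)) {
    cohort_summary <- stage("cohort-summary", summarize_cohort(plans))
    screening <- stage("screening", screen_predictors(plans))
    keep <- match(deliverable$plan_id, plans$plan_id)
    anova_block <- lapply(config$anova_criteria, function(col) {
      factors <- cbind(data.frame(site = plans$site[keep]),
                       plans[keep, screening$included, drop = FALSE])
      rep_ <- stage("anova", nway_anova(deliverable[[col]], factors))
      list(criteria = col, p_values = as.list(rep_$p_values))
    })
    names(anova_block) <- config$anova_criteria
  }

  report <- structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    settings = list(
      criteria = config$criteria,
      threshold_percent = config$threshold_percent,
      deliverability_cut = config$deliverability_cut,
      baseline_size = config$baseline_size,
      n_boot = config$n_boot,
      seed = config$seed
    ),
    n_records = nrow(qa),
    n_deliverable = nrow(deliverable),
    gp_summary = {
      cols <- intersect(paste0("gp_", config$criteria), names(qa))
      stats::setNames(lapply(cols, function(col) {
        list(mean = mean(qa[[col]]), sd = stats::sd(qa[[col]]))
      }), cols)
    },
    spc = list(
      period_boundaries = as.character(boundaries),
      periods = lapply(spc$periods, function(p) {
        list(n = p$n, x_bar = p$x_bar, sigma = p$sigma, mr_bar = p$mr_bar,
             al_cs = p$al_cs, tl_cs = p$tl_cs,
             ci_al = unname(p$ci_al), ci_tl = unname(p$ci_tl),
             in_control = p$in_control)
      }),
      drift = spc$drift
    ),
    site_comparison = site_block,
    screening = if (!is.null(screening)) {
      list(included = screening$included, log = screening$log)
    },
    anova = anova_block,
    cohort_summary = if (!is.null(cohort_summary)) {
      list(parameters = cohort_summary$parameters,
           fw_percent = as.list(cohort_summary$fw_percent))
    }
  ), class = "qa_report")
  validate_report(report)
  report
}

#' Write a pipeline report as JSON
#'
#' @param report a `qa_report` from [run_pipeline()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "qa_report"))
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Validate a pipeline report against the bundled schema
#'
#' Structural validation (required keys and value types) against the JSON
#' schema shipped in `inst/extdata/report-schema.json`.
#'
#' @param report a `qa_report` (or equivalent list).
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("extdata", "report-schema.json", package = "tomoqa")
  if (!nzchar(schema_path)) {
    schema_path <- file.path("inst", "extdata", "report-schema.json")
  }
  schema <- jsonlite::read_json(schema_path)
  check_schema(unclass(report), schema, "report")
  invisible(TRUE)
}

# Minimal JSON-schema subset: type, required, properties, items.
check_schema <- function(x, schema, where) {
  type <- schema$type
  ok <- switch(
    type,
    object = is.list(x) && (is.null(names(x)) == FALSE || length(x) == 0L) ||
      is.data.frame(x),
    array = is.list(x) || (is.atomic(x) && length(x) != 1L) || is.data.frame(x),
    number = is.numeric(x) && length(x) == 1L,
    string = is.character(x) && length(x) == 1L,
    boolean = is.logical(x) && length(x) == 1L,
    TRUE
  )
  if (!ok) stop(where, " is not of schema type '", type, "'", call. = FALSE)
  if (type == "object") {
    for (req in schema$required) {
      if (is.null(x[[req]])) stop(where, " is missing required key '", req, "'", call. = FALSE)
    }
    for (nm in names(schema$properties)) {
      if (!is.null(x[[nm]])) check_schema(x[[nm]], schema$properties[[nm]],
                                          paste0(where, ".", nm))
    }
  }
  if (type == "array" && !is.null(schema$items) && !is.data.frame(x)) {
    for (i in seq_along(x)) {
      check_schema(x[[i]], schema$items, paste0(where, "[", i, "]"))
    }
  }
  invisible(TRUE)
}
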