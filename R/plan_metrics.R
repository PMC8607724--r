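#' Treatment time to dose-per-fraction ratio (TTDF)
#'
#' Total delivery time divided by the prescribed dose per fraction, a simple
#' surrogate of plan complexity for helical deliveries (related to the
#' longitudinal target extent and the pitch).
#'
#' @param total_treatment_time_s delivery time in seconds (> 0).
#' @param dose_per_fraction_cGy prescribed dose per fraction in cGy (> 0).
#' @return TTDF in s/cGy.
#' @examples
#' compute_ttdf(300, 200)  # 1.5
#' @export
compute_ttdf <- function(total_treatment_time_s, dose_per_fraction_cGy) {
  if (any(!is.finite(total_treatment_time_s)) || any(total_treatment_time_s <= 0)) {
    stop("treatment time must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(dose_per_fraction_cGy)) || any(dose_per_fraction_cGy <= 0)) {
    stop("dose per fraction must be strictly positive", call. = FALSE)
  }
  total_treatment_time_s / dose_per_fraction_cGy
}

#' Leaf-open-time distribution descriptors
#'
#' Minimum, arithmetic mean, maximum and sample standard deviation (n - 1
#' denominator) of a plan's leaf-open-time values. The LOT values are treated
#' as one flat array over all projections and leaves. A singleton array gets
#' sd = 0 by convention so degenerate plans remain processable.
#'
#' @param lot_ms numeric vector of leaf open times in ms (non-empty, > 0).
#' @return list with `min_lot_ms`, `mean_lot_ms`, `max_lot_ms`, `sd_lot_ms`.
#' @examples
#' lot_descriptors(c(100, 200, 300))
#' @export
lot_descriptors <- function(lot_ms) {
  if (length(lot_ms) == 0L) stop("LOT array is empty", call. = FALSE)
  if (any(!is.finite(lot_ms)) || any(lot_ms <= 0)) {
    stop("LOT values must be finite and positive", call. = FALSE)
  }
  list(
    min_lot_ms = min(lot_ms),
    mean_lot_ms = mean(lot_ms),
    max_lot_ms = max(lot_ms),
    sd_lot_ms = if (length(lot_ms) == 1L) 0 else stats::sd(lot_ms)
  )
}

# Treatment sites used to stratify the cohort.
PLAN_SITES <- c("abdomen", "brain", "head_and_neck", "lungs", "pelvis",
                "prostate", "others")
FIELD_WIDTHS_MM <- c(10, 25, 50)

# Numeric planning parameters summarised per cohort (Table-style report).
PLAN_PARAMETERS <- c(
  "dose_per_fraction_cGy", "mf", "pitch", "gantry_period_s",
  "total_treatment_time_s", "ttdf_s_per_cGy", "min_lot_ms", "mean_lot_ms",
  "max_lot_ms", "sd_lot_ms", "couch_speed_mm_s", "couch_travel_mm"
)

# Validate a plans data frame against the plan-record contract.
validate_plan_records <- function(plans) {
  needed <- c("plan_id", "site", "field_width_mm", PLAN_PARAMETERS)
  missing <- setdiff(needed, names(plans))
  if (length(missing)) {
    stop("plan records are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(plans$site %in% PLAN_SITES)) {
    stop("unknown treatment site(s): ",
         paste(setdiff(unique(plans$site), PLAN_SITES), collapse = ", "),
         call. = FALSE)
  }
  if (!all(plans$field_width_mm %in% FIELD_WIDTHS_MM)) {
    stop("field width must be one of ", paste(FIELD_WIDTHS_MM, collapse = "/"),
         " mm", call. = FALSE)
  }
  for (p in PLAN_PARAMETERS) {
    if (any(!is.finite(plans[[p]])) || any(plans[[p]] < 0)) {
      stop("parameter ", p, " contains non-finite or negative values", call. = FALSE)
    }
  }
  invisible(plans)
}

#' Cohort summary of planning parameters
#'
#' Mean, standard deviation (n - 1) and range of every numeric planning
#' parameter, plus the percentage split of the jaw field width across its
#' 10/25/50 mm classes — the layout used to characterise a QA population.
#'
#' @param plans data frame of plan records (one row per plan) with the
#'   standard parameter columns; see [make_plan_cohort()].
#' @return list with `parameters` (data frame: parameter, mean, sd, min, max)
#'   and `fw_percent` (named percentages for 10/25/50 mm).
#' @export
summarize_cohort <- function(plans) {
  if (nrow(plans) < 2L) stop("cohort summary needs at least 2 plans", call. = FALSE)
  validate_plan_records(plans)
  stats_rows <- lapply(PLAN_PARAMETERS, function(p) {
    v <- plans[[p]]
    data.frame(parameter = p, mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  })
  fw <- vapply(FIELD_WIDTHS_MM,
               function(w) 100 * mean(plans$field_width_mm == w), 1.0)
  names(fw) <- paste0(FIELD_WIDTHS_MM, "mm")
  list(parameters = do.call(rbind, stats_rows), fw_percent = fw)
}

#' Read / write plan records
#'
#' Plans travel as a CSV with one row per plan and columns named as the plan
#' record fields; leaf-open-time arrays live in a sidecar CSV in long format
#' (`plan_id, lot_ms`). When a sidecar is given, the LOT descriptor columns
#' are recomputed from it.
#'
#' @param plans_csv path to the plans CSV.
#' @param lots_csv optional path to the LOT sidecar CSV.
#' @return data frame of validated plan records.
#' @export
read_plan_cohort <- function(plans_csv, lots_csv = NULL) {
  plans <- utils::read.csv(plans_csv, stringsAsFactors = FALSE)
  if (!is.null(lots_csv)) {
    lots <- utils::read.csv(lots_csv, stringsAsFactors = FALSE)
    if (!all(c("plan_id", "lot_ms") %in% names(lots))) {
      stop("LOT sidecar must have columns plan_id, lot_ms", call. = FALSE)
    }
    by_plan <- split(lots$lot_ms, lots$plan_id)
    for (i in seq_len(nrow(plans))) {
      id <- as.character(plans$plan_id[i])
      if (!id %in% names(by_plan)) {
        stop("no LOT values for plan ", id, " in sidecar", call. = FALSE)
      }
      d <- lot_descriptors(by_plan[[id]])
      plans$min_lot_ms[i] <- d$min_lot_ms
      plans$mean_lot_ms[i] <- d$mean_lot_ms
      plans$max_lot_ms[i] <- d$max_lot_ms
      plans$sd_lot_ms[i] <- d$sd_lot_ms
    }
  }
  validate_plan_records(plans)
}

#' @rdname read_plan_cohort
#' @param plans data frame of plan records to write.
#' @export
write_plan_cohort <- function(plans, plans_csv) {
  validate_plan_records(plans)
  utils::write.csv(plans, plans_csv, row.names = FALSE)
  invisible(plans_csv)
}
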