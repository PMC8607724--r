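# TG-218 statistical process control for gamma passing rates.
#
# Clinic-specific limits on an individuals / moving-range chart:
#   AL_cs = 100 - 3 * sqrt(sigma^2 + (xbar - 100)^2)
#   TL_cs = xbar - 2.660 * mRbar
# where xbar and sigma are the mean and (n - 1) standard deviation of the
# GP% series over the investigation period and mRbar is the mean moving
# range. 2.660 = 3 / d2 with d2 = 1.128, the standard individuals-chart
# constant.

QA_GP_COLUMNS <- c("gp_3G2", "gp_3L2", "gp_3G3", "gp_3L3")

validate_qa_records <- function(records, require_all_criteria = FALSE) {
  needed <- c("plan_id", "date", "gp_3G2")
  if (require_all_criteria) needed <- c("plan_id", "date", QA_GP_COLUMNS)
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("QA records are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(QA_GP_COLUMNS, names(records))) {
    v <- records[[col]]
    bad <- which(!is.finite(v) | v < 0 | v > 100)
    if (length(bad)) {
      stop("record ", records$plan_id[bad[1]], " has an invalid ", col,
           " value (", v[bad[1]], "); GP% must lie in [0, 100]", call. = FALSE)
    }
  }
  invisible(records)
}

#' Keep only clinically deliverable QA records
#'
#' A plan is clinically deliverable when its GP% under the 3%/2 mm global
#' criteria strictly exceeds 90% (the universal action limit). Only such
#' plans enter the control-limit computation; failing plans stay in the
#' database but are excluded from SPC.
#'
#' @param records data frame of QA records with at least `plan_id`, `date`
#'   and `gp_3G2`.
#' @return the deliverable subset, in the original order.
#' @export
filter_deliverable <- function(records) {
  if (nrow(records) == 0L) return(records)
  validate_qa_records(records)
  if (anyNA(records$gp_3G2)) {
    bad <- records$plan_id[which(is.na(records$gp_3G2))[1]]
    stop("record ", bad, " has no 3%/2 mm global GP% value", call. = FALSE)
  }
  records[records$gp_3G2 > 90, , drop = FALSE]
}

#' Clinic-specific action limit
#'
#' \eqn{AL_{cs} = 100 - 3 \sqrt{\sigma^2 + (\bar{x} - 100)^2}} for a process
#' with GP% mean `x_bar` and standard deviation `sigma`.
#'
#' @param x_bar mean GP% of the period (<= 100).
#' @param sigma standard deviation of GP% (>= 0).
#' @return the action limit in percent.
#' @examples
#' action_limit(97.6, 2.6)  # 89.385 -> 89.4 at one decimal
#' @export
action_limit <- function(x_bar, sigma) {
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  if (any(x_bar > 100)) stop("x_bar cannot exceed 100 (it is a passing rate)", call. = FALSE)
  100 - 3 * sqrt(sigma^2 + (x_bar - 100)^2)
}

#' Mean moving range of an individuals chart
#'
#' Mean of the absolute differences between consecutive observations, taken
#' in delivery order.
#'
#' @param series numeric GP% series of length >= 2, in delivery order.
#' @return mean moving range.
#' @export
moving_range_mean <- function(series) {
  if (length(series) < 2L) {
    stop("moving range needs at least 2 observations", call. = FALSE)
  }
  mean(abs(diff(series)))
}

#' Clinic-specific tolerance limit
#'
#' \eqn{TL_{cs} = \bar{x} - 2.660\,\bar{mR}} with the individuals-chart
#' constant 2.660 fixed.
#'
#' @inheritParams moving_range_mean
#' @return the tolerance limit in percent.
#' @examples
#' tolerance_limit(c(95, 97, 93))  # 95 - 2.660 * 3 = 87.02
#' @export
tolerance_limit <- function(series) {
  mean(series) - 2.660 * moving_range_mean(series)
}

spc_statistic <- function(series, statistic = c("action", "tolerance")) {
  statistic <- match.arg(statistic)
  if (statistic == "action") {
    action_limit(mean(series), stats::sd(series))
  } else {
    tolerance_limit(series)
  }
}

#' Bootstrap percentile confidence interval for a control limit
#'
#' Nonparametric bootstrap of the action- or tolerance-limit statistic:
#' sequences are resampled with replacement and, for the order-dependent
#' tolerance limit, used in drawn order. The interval is the percentile
#' interval of the bootstrap distribution.
#'
#' @param series GP% series of length >= 2, in delivery order.
#' @param statistic `"action"` or `"tolerance"`.
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed (required; results are reproducible given seed).
#' @return numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(series, statistic = c("action", "tolerance"),
                         n_boot = 10000, level = 0.95, seed) {
  statistic <- match.arg(statistic)
  n <- length(series)
  if (n < 2L) stop("bootstrap needs a series of length >= 2", call. = FALSE)
  if (missing(seed)) stop("a seed must be supplied", call. = FALSE)
  stats_boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), nrow = n_boot)
    X <- matrix(series[idx], nrow = n_boot)
    m1 <- rowMeans(X)
    if (statistic == "action") {
      v <- rowSums((X - m1)^2) / (n - 1)
      100 - 3 * sqrt(v + (m1 - 100)^2)
    } else {
      mr <- rowMeans(abs(X[, -1, drop = FALSE] - X[, -n, drop = FALSE]))
      m1 - 2.660 * mr
    }
  })
  ci <- stats::quantile(stats_boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  c(lo = ci[1], hi = ci[2])
}

#' Evaluate control limits for one monitoring period
#'
#' Computes the period's GP% mean, standard deviation (n - 1), mean moving
#' range, clinic-specific action and tolerance limits and their bootstrap
#' confidence intervals. The baseline period uses the first 40 records in
#' date order, mirroring the recommended initial evaluation; the period is
#' in control when no record lies below the period's action limit.
#'
#' @param records deliverability-filtered QA records (see
#'   [filter_deliverable()]) with `date` and `gp_3G2` columns.
#' @param baseline if TRUE, require >= 40 records and use the first 40.
#' @param seed integer seed for the bootstrap.
#' @param n_boot bootstrap resamples.
#' @param gp_column which GP% column the chart tracks (default `gp_3G2`).
#' @return object of class `spc_limits`: `n`, `x_bar`, `sigma`, `mr_bar`,
#'   `al_cs`, `tl_cs`, `ci_al`, `ci_tl`, `in_control`.
#' @export
evaluate_period <- function(records, baseline = FALSE, seed, n_boot = 10000,
                            gp_column = "gp_3G2") {
  validate_qa_records(records)
  if (missing(seed)) stop("a seed must be supplied", call. = FALSE)
  records <- records[order(records$date), , drop = FALSE]
  if (baseline) {
    if (nrow(records) < 40L) {
      stop("a baseline period requires at least 40 records (got ",
           nrow(records), ")", call. = FALSE)
    }
    records <- records[seq_len(40L), , drop = FALSE]
  }
  series <- records[[gp_column]]
  if (length(series) < 2L) {
    stop("a monitoring period requires at least 2 records", call. = FALSE)
  }
  x_bar <- mean(series)
  sigma <- stats::sd(series)
  mr_bar <- moving_range_mean(series)
  al <- action_limit(x_bar, sigma)
  tl <- tolerance_limit(series)
  # independent sub-seeds for the two bootstrap runs, derived from `seed`
  ci_al <- bootstrap_ci(series, "action", n_boot = n_boot, seed = seed)
  ci_tl <- bootstrap_ci(series, "tolerance", n_boot = n_boot,
                        seed = (as.integer(seed) + 1L) %% .Machine$integer.max)
  structure(
    list(n = length(series), x_bar = x_bar, sigma = sigma, mr_bar = mr_bar,
         al_cs = al, tl_cs = tl, ci_al = ci_al, ci_tl = ci_tl,
         in_control = !any(series < al)),
    class = "spc_limits"
  )
}

#' @export
print.spc_limits <- function(x, ...) {
  cat(sprintf(
    "<spc_limits> n = %d, GP%% %.2f +/- %.2f, AL_cs %.2f [%.2f, %.2f], TL_cs %.2f [%.2f, %.2f], %s\n",
    x$n, x$x_bar, x$sigma, x$al_cs, x$ci_al[1], x$ci_al[2],
    x$tl_cs, x$ci_tl[1], x$ci_tl[2],
    if (x$in_control) "in control" else "OUT OF CONTROL"))
  invisible(x)
}

#' Periodic monitoring of the QA process
#'
#' Splits the (deliverability-filtered) QA series into consecutive
#' monitoring periods, evaluates the control limits per period (the first
#' period is the baseline and uses its first 40 records), and flags a drift
#' between consecutive periods when their bootstrap confidence intervals for
#' the action limit or the tolerance limit are disjoint.
#'
#' @param records deliverability-filtered QA records.
#' @param period_boundaries increasing vector of boundary dates; period i
#'   collects records with `boundaries[i] <= date < boundaries[i + 1]`.
#' @param seed integer seed.
#' @param n_boot bootstrap resamples.
#' @param gp_column GP% column tracked by the chart.
#' @return object of class `spc_monitor`: `periods` (list of `spc_limits`),
#'   `drift` (data frame: from, to, drift_al, drift_tl, drift).
#' @export
monitor <- function(records, period_boundaries, seed, n_boot = 10000,
                    gp_column = "gp_3G2") {
  validate_qa_records(records)
  if (missing(seed)) stop("a seed must be supplied", call. = FALSE)
  nb <- length(period_boundaries)
  if (nb < 2L) stop("period boundaries must define at least one period", call. = FALSE)
  if (is.unsorted(period_boundaries, strictly = TRUE)) {
    stop("period boundaries must be strictly increasing", call. = FALSE)
  }
  periods <- vector("list", nb - 1L)
  for (i in seq_len(nb - 1L)) {
    in_p <- records$date >= period_boundaries[i] &
      records$date < period_boundaries[i + 1L]
    if (!any(in_p)) {
      stop("empty monitoring period [", period_boundaries[i], ", ",
           period_boundaries[i + 1L], ")", call. = FALSE)
    }
    periods[[i]] <- evaluate_period(
      records[in_p, , drop = FALSE], baseline = (i == 1L),
      seed = (as.integer(seed) + 2L * i) %% .Machine$integer.max,
      n_boot = n_boot, gp_column = gp_column
    )
  }
  drift <- NULL
  if (length(periods) > 1L) {
    disjoint <- function(a, b) a[2] < b[1] || b[2] < a[1]
    rows <- lapply(seq_len(length(periods) - 1L), function(i) {
      d_al <- disjoint(periods[[i]]$ci_al, periods[[i + 1L]]$ci_al)
      d_tl <- disjoint(periods[[i]]$ci_tl, periods[[i + 1L]]$ci_tl)
      data.frame(from = i, to = i + 1L, drift_al = d_al, drift_tl = d_tl,
                 drift = d_al || d_tl)
    })
    drift <- do.call(rbind, rows)
  } else {
    drift <- data.frame(from = integer(0), to = integer(0),
                        drift_al = logical(0), drift_tl = logical(0),
                        drift = logical(0))
  }
  structure(list(periods = periods, drift = drift), class = "spc_monitor")
}

#' @export
print.spc_monitor <- function(x, ...) {
  cat("<spc_monitor> ", length(x$periods), " periods\n", sep = "")
  for (i in seq_along(x$periods)) {
    cat(sprintf("  period %d: ", i)); print(x$periods[[i]])
  }
  if (any(x$drift$drift)) {
    flagged <- x$drift[x$drift$drift, ]
    cat("  drift flagged between periods: ",
        paste(sprintf("%d->%d", flagged$from, flagged$to), collapse = ", "), "\n")
  } else {
    cat("  no drift flagged\n")
  }
  invisible(x)
}
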