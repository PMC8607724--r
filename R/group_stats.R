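# Cohort statistics: site-wise GP% comparison (Kruskal-Wallis + Bonferroni
# post-hoc rank-sum tests) and planning-parameter influence screening +
# n-way ANOVA. The rank tests and linear-model machinery are base R; this
# module defines the QA-specific contracts and reporting around them.

as_group_list <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be a named list of numeric vectors", call. = FALSE)
  }
  lapply(groups, as.numeric)
}

#' Kruskal-Wallis comparison of GP% across groups
#'
#' Rank-based H statistic with tie correction; the p-value comes from the
#' chi-square distribution with k - 1 degrees of freedom.
#'
#' @param groups named list mapping group label (e.g. treatment site) to its
#'   GP% values; at least 2 groups with at least 2 values each.
#' @return object of class `qa_test_report` with `test`, `statistic`, `df`,
#'   `p_value` and `groups`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 2L)) {
    stop("group '", names(groups)[which(sizes < 2L)[1]],
         "' has fewer than 2 values", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), sizes), levels = names(groups))
  if (stats::var(values) == 0) {
    # fully tied response: tie-corrected H degenerates to 0/0; by convention
    # there is no evidence against homogeneity
    stat <- 0; df <- length(groups) - 1L; p <- 1
  } else {
    kt <- stats::kruskal.test(values, labels)
    stat <- unname(kt$statistic); df <- unname(kt$parameter); p <- kt$p.value
  }
  structure(
    list(test = "Kruskal-Wallis", statistic = stat, df = df, p_value = p,
         groups = names(groups)),
    class = "qa_test_report"
  )
}

#' Bonferroni-adjusted pairwise post-hoc comparisons
#'
#' All k(k-1)/2 pairwise two-sided Wilcoxon rank-sum tests with adjusted
#' p = min(1, m * p_raw), m the number of pairs. Intended as the follow-up to
#' a significant [kruskal_wallis()] result (the pipeline, not this function,
#' enforces that ordering).
#'
#' @inheritParams kruskal_wallis
#' @return object of class `qa_test_report` with symmetric matrices
#'   `p_raw` and `p_adjusted`, and `m` (the number of comparisons).
#' @export
posthoc_bonferroni <- function(groups) {
  groups <- as_group_list(groups)
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  labs <- names(groups)
  m <- k * (k - 1L) / 2L
  p_raw <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      p <- suppressWarnings(
        stats::wilcox.test(groups[[i]], groups[[j]], exact = FALSE)$p.value
      )
      p_raw[i, j] <- p_raw[j, i] <- p
    }
  }
  p_adj <- p_raw
  p_adj[] <- pmin(1, m * p_raw)   # pmin would drop the matrix shape
  diag(p_raw) <- NA_real_
  diag(p_adj) <- NA_real_
  structure(
    list(test = "pairwise Wilcoxon rank-sum, Bonferroni",
         p_raw = p_raw, p_adjusted = p_adj, m = m, groups = labs),
    class = "qa_test_report"
  )
}

# Fixed screening order: the parameters a complexity analysis reports first
# (MF, TTDF, LOT descriptors, pitch, gantry period, couch speed), then the
# remaining raw plan fields. Earlier parameters win ties.
SCREEN_ORDER <- c(
  "mf", "ttdf_s_per_cGy", "mean_lot_ms", "max_lot_ms", "pitch",
  "gantry_period_s", "couch_speed_mm_s", "min_lot_ms", "sd_lot_ms",
  "dose_per_fraction_cGy", "total_treatment_time_s", "couch_travel_mm"
)

#' Screen planning parameters for mutual correlation
#'
#' Greedy forward screening in a fixed, documented parameter order: a
#' parameter joins the included set unless its absolute Pearson correlation
#' with an already-included parameter reaches `r_threshold`. The exclusion
#' log records the culprit pair, the correlation and its test p-value.
#' Constant (zero-variance) parameters are excluded with a reason rather
#' than raising an error.
#'
#' @param records data frame of plan records (numeric parameter columns).
#' @param r_threshold exclusion threshold on |r| (default 0.8).
#' @param order parameter screening order; defaults to the package's fixed
#'   order (complexity surrogates first).
#' @return list with `included` (character vector) and `log` (data frame:
#'   parameter, excluded, reason, versus, r, p).
#' @export
screen_predictors <- function(records, r_threshold = 0.8, order = SCREEN_ORDER) {
  if (nrow(records) < 3L) stop("screening needs at least 3 records", call. = FALSE)
  order <- intersect(order, names(records))
  if (length(order) == 0L) stop("no screenable parameter columns found", call. = FALSE)
  included <- character(0)
  log_rows <- list()
  for (p in order) {
    v <- records[[p]]
    if (stats::sd(v) == 0) {
      log_rows[[p]] <- data.frame(parameter = p, excluded = TRUE,
                                  reason = "constant (zero variance)",
                                  versus = NA_character_, r = NA_real_,
                                  p = NA_real_, stringsAsFactors = FALSE)
      next
    }
    culprit <- NULL
    for (q in included) {
      r <- stats::cor(v, records[[q]])
      if (abs(r) >= r_threshold) {
        pv <- stats::cor.test(v, records[[q]])$p.value
        culprit <- list(q = q, r = r, p = pv)
        break
      }
    }
    if (is.null(culprit)) {
      included <- c(included, p)
      log_rows[[p]] <- data.frame(parameter = p, excluded = FALSE,
                                  reason = "included", versus = NA_character_,
                                  r = NA_real_, p = NA_real_,
                                  stringsAsFactors = FALSE)
    } else {
      log_rows[[p]] <- data.frame(
        parameter = p, excluded = TRUE,
        reason = sprintf("|r| = %.3f >= %.2f vs %s", abs(culprit$r),
                         r_threshold, culprit$q),
        versus = culprit$q, r = culprit$r, p = culprit$p,
        stringsAsFactors = FALSE)
    }
  }
  list(included = included, log = do.call(rbind, unname(log_rows)))
}

#' n-way ANOVA of GP% on site and screened planning parameters
#'
#' Main-effects-only linear model with Type II (marginal) sums of squares:
#' each factor's p-value compares the full main-effects model against the
#' model without that factor. Continuous parameters are discretised into
#' tertiles before entering the model.
#'
#' @param response numeric GP% vector.
#' @param factors data frame of predictors aligned with `response`:
#'   categorical columns (e.g. `site`) are used as-is, numeric columns are
#'   binned into tertiles.
#' @return object of class `qa_test_report` with `p_values` (named per
#'   factor) and the underlying ANOVA `table`.
#' @export
nway_anova <- function(response, factors) {
  if (!is.data.frame(factors) || ncol(factors) < 1L) {
    stop("`factors` must be a data frame with at least one column", call. = FALSE)
  }
  if (length(response) != nrow(factors)) {
    stop("response and factors must have the same length", call. = FALSE)
  }
  binned <- factors
  for (nm in names(binned)) {
    v <- binned[[nm]]
    if (is.numeric(v)) {
      br <- unique(stats::quantile(v, probs = c(0, 1/3, 2/3, 1), names = FALSE))
      if (length(br) < 3L) {
        stop("factor '", nm, "' has a single level after tertile binning",
             call. = FALSE)
      }
      binned[[nm]] <- cut(v, breaks = br, include.lowest = TRUE,
                          labels = paste0("T", seq_len(length(br) - 1L)))
    } else {
      binned[[nm]] <- factor(v)
      if (nlevels(droplevels(binned[[nm]])) < 2L) {
        stop("factor '", nm, "' has a single level", call. = FALSE)
      }
      binned[[nm]] <- droplevels(binned[[nm]])
    }
  }
  n_param <- sum(vapply(binned, nlevels, 1L) - 1L) + 1L
  if (length(response) <= n_param) {
    stop("not enough observations (", length(response),
         ") for the model's ", n_param, " parameters", call. = FALSE)
  }
  dat <- cbind(data.frame(.gp = response), binned)
  fit <- stats::lm(.gp ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    hit <- unique(unlist(lapply(names(binned), function(nm) {
      if (any(startsWith(bad, nm))) nm else NULL
    })))
    stop("singular design; aliased factor(s): ", paste(hit, collapse = ", "),
         call. = FALSE)
  }
  # Type II: for main-effects-only models, drop-one F tests are the marginal
  # (Type II) tests.
  dr <- stats::drop1(fit, test = "F")
  tab <- dr[-1, , drop = FALSE]
  p_values <- stats::setNames(tab[["Pr(>F)"]], rownames(tab))
  structure(
    list(test = "n-way ANOVA (Type II, main effects)", p_values = p_values,
         table = tab),
    class = "qa_test_report"
  )
}

#' @export
print.qa_test_report <- function(x, ...) {
  cat("<qa_test_report> ", x$test, "\n", sep = "")
  if (!is.null(x$p_value)) {
    cat(sprintf("  statistic = %.4g (df = %s), p = %.4g\n",
                x$statistic, format(x$df), x$p_value))
  }
  if (!is.null(x$p_values)) {
    for (nm in names(x$p_values)) {
      cat(sprintf("  %-22s p = %.4g\n", nm, x$p_values[[nm]]))
    }
  }
  if (!is.null(x$p_adjusted)) {
    cat("  ", x$m, " pairwise comparisons (Bonferroni-adjusted)\n", sep = "")
  }
  invisible(x)
}
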