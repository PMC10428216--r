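#' Welch's unequal-variances t-test
#'
#' Two-sample location test that does not assume equal variances or equal
#' sample sizes:
#' \deqn{t = \frac{\bar x - \bar y}{\sqrt{s_x^2/n_x + s_y^2/n_y}}}
#' with real-valued Welch–Satterthwaite degrees of freedom and a two-sided
#' p-value from Student's t distribution. Sample variances use the
#' \eqn{n - 1} denominator.
#'
#' @param x,y Numeric samples, each with at least 2 values; at least one
#'   sample must have nonzero variance.
#' @return An object of class `welch_result`: a list with `statistic`,
#'   `df`, `p_value`, `mean_x`, `mean_y`, `n_x`, `n_y`.
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5, 6, 7))
welch_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    rlang::abort("each sample needs at least 2 values", class = "kinoflex_stats_error")
  }
  if (anyNA(x) || anyNA(y)) rlang::abort("samples must not contain NA", class = "kinoflex_stats_error")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    rlang::abort("both samples have zero variance: t statistic undefined",
                 class = "kinoflex_stats_error")
  }
  nx <- length(x); ny <- length(y)
  se2x <- vx / nx; se2y <- vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
  p <- 2 * pt(-abs(t_stat), df)
  structure(list(statistic = t_stat, df = df, p_value = p,
                 mean_x = mean(x), mean_y = mean(y), n_x = nx, n_y = ny),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t = %.4f, df = %.3f, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  means: %.4g vs %.4g (n = %d, %d)\n", x$mean_x, x$mean_y, x$n_x, x$n_y))
  invisible(x)
}

#' @rdname welch_t_test
#' @param x A `welch_result`.
#' @param ... Unused.
#' @method tidy welch_result
#' @export
tidy.welch_result <- function(x, ...) {
  tibble::tibble(estimate = x$mean_x - x$mean_y, statistic = x$statistic,
                 df = x$df, p.value = x$p_value,
                 mean_x = x$mean_x, mean_y = x$mean_y, n_x = x$n_x, n_y = x$n_y)
}

#' Active-vs-inactive group comparison per pocket and metric
#'
#' Runs one Welch test per (pocket, metric) cell of a long per-system table,
#' comparing the active against the inactive systems. Pockets missing one
#' class entirely are reported as untestable rather than dropped. P-values
#' are reported raw (no multiple-testing correction) by default, matching
#' the convention of reporting each pocket's evidence separately; a
#' Bonferroni adjustment over pockets can be switched on.
#'
#' @param values Data frame with columns `system`, `label`
#'   (`active`/`inactive`), `pocket`, `metric`, `value`.
#' @param threshold Significance threshold (default 0.05).
#' @param bonferroni If `TRUE`, multiply p-values by the number of testable
#'   pockets within each metric (capped at 1) before flagging.
#' @return A tibble of class `comparison_report`: one row per (pocket,
#'   metric) with group means/sizes, `statistic`, `df`, `p_value`,
#'   `significant` and `testable`.
#' @export
compare_groups <- function(values, threshold = 0.05, bonferroni = FALSE) {
  needed <- c("system", "label", "pocket", "metric", "value")
  if (!all(needed %in% names(values))) {
    stop_field("values", paste("needs columns", paste(needed, collapse = ", ")))
  }
  values$label <- check_labels(values$label, "label")
  check_prob(threshold, "threshold")
  out <- values |>
    dplyr::group_by(.data$pocket, .data$metric) |>
    dplyr::group_modify(function(df, key) {
      a <- df$value[df$label == "active"]
      i <- df$value[df$label == "inactive"]
      base <- tibble::tibble(
        n_active = length(a), n_inactive = length(i),
        mean_active = if (length(a)) mean(a) else NA_real_,
        mean_inactive = if (length(i)) mean(i) else NA_real_
      )
      res <- tryCatch(welch_t_test(a, i), kinoflex_stats_error = function(e) NULL)
      if (is.null(res)) {
        dplyr::mutate(base, statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_, testable = FALSE)
      } else {
        dplyr::mutate(base, statistic = res$statistic, df = res$df,
                      p_value = res$p_value, testable = TRUE)
      }
    }) |>
    dplyr::ungroup()
  if (bonferroni) {
    out <- out |>
      dplyr::group_by(.data$metric) |>
      dplyr::mutate(p_value = pmin(1, .data$p_value * sum(.data$testable))) |>
      dplyr::ungroup()
  }
  out$significant <- !is.na(out$p_value) & out$p_value < threshold
  structure(out, class = c("comparison_report", class(out)), threshold = threshold)
}
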