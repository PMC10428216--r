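#' Repeated random-split evaluation of the stump classifier
#'
#' Repeats a random train/validation split (train size =
#' `floor(n * train_fraction)`), fits a stump on the training rows and
#' scores balanced accuracy on the validation rows. Splits are simple
#' random draws; a draw leaving either side with a single class is redrawn
#' (bounded retries), since neither the fit nor the balanced accuracy is
#' defined on one-class data. Fully reproducible from `seed`: repeat `r`
#' uses RNG seed `seed + r`.
#'
#' With 43 systems and the default 0.7 fraction every repeat uses 30
#' training and 13 validation rows.
#'
#' @param panel A `fluct_panel` tibble.
#' @param train_fraction Fraction of rows used for training (default 0.7).
#' @param repeats Number of random splits (default 100).
#' @param seed Base integer seed.
#' @param max_redraws Maximum redraws per repeat before erroring.
#' @return An object of class `stump_evaluation`: summary statistics
#'   (`mean_balanced_accuracy`, `sd_balanced_accuracy` — population sd),
#'   split sizes, per-repeat `records` and `column_frequency` (fraction of
#'   repeats selecting each column; sums to 1).
#' @export
resampled_evaluation <- function(panel, train_fraction = 0.7, repeats = 100L,
                                 seed = 1L, max_redraws = 100L) {
  labels <- check_labels(panel$label)
  if (length(unique(labels)) < 2L) {
    rlang::abort("panel must contain both classes", class = "kinoflex_fit_error")
  }
  n <- nrow(panel)
  if (n < 4L) rlang::abort("need at least 4 rows to split", class = "kinoflex_fit_error")
  check_scalar_number(train_fraction, "train_fraction", min = 0, strict_min = TRUE)
  if (train_fraction >= 1) stop_field("train_fraction", "must be < 1")
  repeats <- check_count(repeats, "repeats", min = 1L)
  n_train <- floor(n * train_fraction)
  if (n_train < 2L || n_train > n - 2L) {
    stop_field("train_fraction", "leaves fewer than 2 rows on one side")
  }

  one_repeat <- function(r) {
    withr::with_seed(seed + r, {
      for (try in seq_len(max_redraws)) {
        idx <- sample.int(n, n_train)
        tr_lab <- labels[idx]; va_lab <- labels[-idx]
        if (length(unique(tr_lab)) == 2L && length(unique(va_lab)) == 2L) {
          model <- fit_stump(panel[idx, , drop = FALSE])
          ba <- balanced_accuracy(va_lab, predict(model, panel[-idx, , drop = FALSE]))
          return(tibble::tibble(repeat_id = r, seed = seed + r,
                                column = model$column, threshold = model$threshold,
                                orientation = model$orientation,
                                balanced_accuracy = ba))
        }
      }
      rlang::abort(sprintf("repeat %d: could not draw a two-class split in %d tries",
                           r, max_redraws), class = "kinoflex_fit_error")
    })
  }
  records <- purrr::map_dfr(seq_len(repeats), one_repeat)

  ba <- records$balanced_accuracy
  freq <- records |>
    dplyr::count(.data$column, name = "n") |>
    dplyr::mutate(frequency = .data$n / repeats) |>
    dplyr::select("column", "frequency") |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$column)

  structure(
    list(repeats = repeats, train_fraction = train_fraction,
         n_train = n_train, n_validation = n - n_train,
         mean_balanced_accuracy = mean(ba),
         sd_balanced_accuracy = sqrt(mean((ba - mean(ba))^2)),
         records = records, column_frequency = freq, seed = seed),
    class = "stump_evaluation"
  )
}

#' @export
print.stump_evaluation <- function(x, ...) {
  cat(sprintf("<stump_evaluation> %d repeats, %d train / %d validation rows\n",
              x$repeats, x$n_train, x$n_validation))
  cat(sprintf("  balanced accuracy %.2f%% ± %.2f%%\n",
              100 * x$mean_balanced_accuracy, 100 * x$sd_balanced_accuracy))
  top <- utils::head(x$column_frequency, 3)
  cat("  top columns:", paste(sprintf("%s (%.0f%%)", top$column, 100 * top$frequency),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @rdname resampled_evaluation
#' @param x A `stump_evaluation`.
#' @param ... Unused.
#' @method tidy stump_evaluation
#' @export
tidy.stump_evaluation <- function(x, ...) x$records

#' @rdname resampled_evaluation
#' @method glance stump_evaluation
#' @export
glance.stump_evaluation <- function(x, ...) {
  tibble::tibble(repeats = x$repeats, train_fraction = x$train_fraction,
                 n_train = x$n_train, n_validation = x$n_validation,
                 mean_balanced_accuracy = x$mean_balanced_accuracy,
                 sd_balanced_accuracy = x$sd_balanced_accuracy,
                 modal_column = modal_column(x))
}

# Most frequently selected column; ties resolved toward panel column order
# is not available here, so ties resolve toward the lexicographically
# smallest numeric column index (c2 before c10).
modal_column <- function(evaluation) {
  freq <- evaluation$column_frequency
  top <- freq$column[freq$frequency == max(freq$frequency)]
  idx <- suppressWarnings(as.integer(sub("^c", "", top)))
  if (!anyNA(idx)) top[order(idx)][1] else sort(top)[1]
}

#' Histogram of per-repeat balanced accuracies
#'
#' @param object A `stump_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stump_evaluation
#' @export
autoplot.stump_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$records, ggplot2::aes(x = .data$balanced_accuracy)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_balanced_accuracy,
                        linetype = "dashed") +
    ggplot2::labs(x = "Balanced accuracy (validation)", y = "Repeats") +
    ggplot2::theme_minimal()
}

#' Feature ablation cascade
#'
#' Iteratively evaluates the stump by repeated holdout, records the modal
#' (most frequently selected) column, removes it from the panel, and
#' repeats. On a panel whose signal residue has correlated neighbours the
#' cascade exposes the backup features in correlation order before
#' accuracy collapses to chance.
#'
#' @inheritParams resampled_evaluation
#' @param rounds Number of ablation rounds (must be < number of feature
#'   columns).
#' @return An object of class `ablation_report`: a `rounds` tibble
#'   (`round`, `removed_before`, `selected_column`,
#'   `mean_balanced_accuracy`, `sd_balanced_accuracy`) plus the underlying
#'   `evaluations` list.
#' @export
ablation_cascade <- function(panel, rounds = 3L, train_fraction = 0.7,
                             repeats = 100L, seed = 1L) {
  rounds <- check_count(rounds, "rounds", min = 1L)
  feats <- panel_feature_names(panel)
  if (rounds >= length(feats)) stop_field("rounds", "must be < number of feature columns")
  removed <- character(0)
  rows <- vector("list", rounds)
  evals <- vector("list", rounds)
  current <- panel
  for (k in seq_len(rounds)) {
    ev <- resampled_evaluation(current, train_fraction = train_fraction,
                               repeats = repeats,
                               seed = seed + (k - 1L) * (repeats + 1L))
    sel <- modal_column(ev)
    rows[[k]] <- tibble::tibble(
      round = k, removed_before = list(removed), selected_column = sel,
      mean_balanced_accuracy = ev$mean_balanced_accuracy,
      sd_balanced_accuracy = ev$sd_balanced_accuracy
    )
    evals[[k]] <- ev
    removed <- c(removed, sel)
    current <- current[, setdiff(names(current), sel), drop = FALSE]
  }
  structure(list(rounds = dplyr::bind_rows(rows), evaluations = evals),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("<ablation_report>\n")
  r <- x$rounds
  for (k in seq_len(nrow(r))) {
    cat(sprintf("  round %d: selected %s, balanced accuracy %.2f%% ± %.2f%%\n",
                r$round[k], r$selected_column[k],
                100 * r$mean_balanced_accuracy[k], 100 * r$sd_balanced_accuracy[k]))
  }
  invisible(x)
}

#' @rdname ablation_cascade
#' @param x An `ablation_report`.
#' @param ... Unused.
#' @method tidy ablation_report
#' @export
tidy.ablation_report <- function(x, ...) {
  dplyr::mutate(x$rounds,
                removed_before = vapply(.data$removed_before,
                                        function(v) paste(v, collapse = ","), ""))
}

#' L1-penalised logistic feature selection
#'
#' Corroborates the stump's choice with the Lasso: fits an L1-penalised
#' logistic regression (active vs inactive) on internally standardised
#' columns and returns the columns with nonzero coefficients ranked by
#' absolute coefficient.
#'
#' @param panel A `fluct_panel` tibble.
#' @param penalty Regularisation strength (glmnet's `lambda`).
#' @return A tibble with `column`, `coefficient` (standardised scale) and
#'   `rank`, ordered by `abs(coefficient)` decreasing. Zero rows if the
#'   penalty shrinks everything away.
#' @export
lasso_select <- function(panel, penalty = 0.05) {
  check_scalar_number(penalty, "penalty", min = 0)
  y <- check_labels(panel$label)
  feats <- panel_feature_names(panel)
  X <- as.matrix(panel[feats])
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) {
    rlang::abort("all feature columns are constant; Lasso is undefined",
                 class = "kinoflex_fit_error")
  }
  Xs <- scale(X)
  Xs[, sds == 0] <- 0
  fit <- glmnet::glmnet(Xs, factor(y, levels = c("inactive", "active")),
                        family = "binomial", alpha = 1, lambda = penalty,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-12, maxit = 1e6)
  beta <- as.numeric(fit$beta)
  keep <- which(beta != 0)
  out <- tibble::tibble(column = feats[keep], coefficient = beta[keep])
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$coefficient)))
  dplyr::mutate(out, rank = dplyr::row_number())
}
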