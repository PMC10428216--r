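#' Fit a one-rule decision stump on a fluctuation panel
#'
#' Exhaustively searches every (column, threshold) pair, where candidate
#' thresholds are the midpoints between consecutive distinct sorted values
#' of each column, and selects the split minimising the weighted Gini
#' impurity. Ties are broken deterministically: lowest column index first,
#' then lowest threshold. The below-threshold side is assigned its majority
#' class (ties to "active"); the above side predicts the complementary
#' class, so the fitted model is a single if-then-else rule on one
#' residue's fluctuation.
#'
#' @param panel A `fluct_panel` tibble (columns `kinase`, `label`, plus
#'   numeric feature columns), restricted to the training rows.
#' @param label_col Name of the label column (default `"label"`).
#' @return An object of class `stump_model`: `column`, `threshold`
#'   (angstrom), `orientation` (class predicted below the threshold),
#'   `train_impurity` (weighted Gini) and `train_balanced_accuracy`.
#' @export
#' @examples
#' p <- tibble::tibble(kinase = paste0("k", 1:4),
#'                     label = c("active", "active", "inactive", "inactive"),
#'                     c1 = c(0.4, 0.5, 1.5, 1.6))
#' fit_stump(p) # threshold 1.0, below -> active
fit_stump <- function(panel, label_col = "label") {
  y <- check_labels(panel[[label_col]], label_col)
  if (length(unique(y)) < 2L) {
    rlang::abort("training data contains a single class; a stump cannot be fit",
                 class = "kinoflex_fit_error")
  }
  feats <- setdiff(names(panel), c("kinase", label_col))
  feats <- feats[vapply(panel[feats], is.numeric, TRUE)]
  if (!length(feats)) rlang::abort("no numeric feature columns", class = "kinoflex_fit_error")
  n <- length(y)
  is_active <- y == "active"

  best <- list(imp = Inf, column = NA_character_, threshold = NA_real_,
               below_active = NA)
  for (j in seq_along(feats)) {
    v <- panel[[feats[j]]]
    ord <- order(v, method = "radix")
    sv <- v[ord]
    a <- cumsum(is_active[ord])
    cut <- which(sv[-n] < sv[-1])        # boundaries between distinct values
    if (!length(cut)) next
    nL <- cut
    aL <- a[cut]
    nR <- n - nL
    aR <- a[n] - aL
    gL <- 1 - (aL / nL)^2 - ((nL - aL) / nL)^2
    gR <- 1 - (aR / nR)^2 - ((nR - aR) / nR)^2
    imp <- (nL / n) * gL + (nR / n) * gR
    k <- which.min(imp)                  # lowest threshold among equal minima
    if (imp[k] < best$imp) {
      thr <- (sv[cut[k]] + sv[cut[k] + 1]) / 2
      below_maj_active <- aL[k] >= nL[k] - aL[k]   # tie -> active
      best <- list(imp = imp[k], column = feats[j], threshold = thr,
                   below_active = below_maj_active)
    }
  }
  if (!is.finite(best$imp)) {
    rlang::abort("all feature columns are constant; no split exists",
                 class = "kinoflex_fit_error")
  }
  model <- structure(
    list(column = best$column, threshold = best$threshold,
         orientation = if (best$below_active) "active" else "inactive",
         train_impurity = best$imp, n_train = n,
         train_balanced_accuracy = NA_real_),
    class = "stump_model"
  )
  model$train_balanced_accuracy <- balanced_accuracy(y, predict(model, panel))
  model
}

#' @export
print.stump_model <- function(x, ...) {
  other <- setdiff(c("active", "inactive"), x$orientation)
  cat(sprintf("<stump_model> if %s < %.4g Å then %s else %s\n",
              x$column, x$threshold, x$orientation, other))
  cat(sprintf("  train Gini %.4f, balanced accuracy %.4f (n = %d)\n",
              x$train_impurity, x$train_balanced_accuracy, x$n_train))
  invisible(x)
}

#' Predict activity labels with a fitted stump
#'
#' @param object A `stump_model`.
#' @param newdata Data frame containing the model's feature column.
#' @param ... Unused.
#' @return Character vector of `"active"`/`"inactive"`.
#' @export
predict.stump_model <- function(object, newdata, ...) {
  v <- newdata[[object$column]]
  if (is.null(v)) stop_field("newdata", paste("missing column", object$column))
  other <- setdiff(c("active", "inactive"), object$orientation)
  ifelse(v < object$threshold, object$orientation, other)
}

#' @rdname fit_stump
#' @param x A `stump_model`.
#' @param ... Unused.
#' @method tidy stump_model
#' @export
tidy.stump_model <- function(x, ...) {
  tibble::tibble(column = x$column, threshold = x$threshold,
                 orientation = x$orientation, train_impurity = x$train_impurity,
                 train_balanced_accuracy = x$train_balanced_accuracy,
                 n_train = x$n_train)
}

#' Balanced accuracy
#'
#' The mean of sensitivity (recall on the active class) and specificity
#' (recall on the inactive class); insensitive to class imbalance.
#'
#' @param y_true,y_pred Character/factor vectors of `"active"`/`"inactive"`
#'   labels of equal length; `y_true` must contain both classes.
#' @return A value in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  y_true <- check_labels(y_true, "y_true")
  y_pred <- check_labels(y_pred, "y_pred")
  if (length(y_true) != length(y_pred)) {
    rlang::abort("y_true and y_pred must have equal length", class = "kinoflex_stats_error")
  }
  if (length(unique(y_true)) < 2L) {
    rlang::abort("y_true contains a single class; sensitivity or specificity is undefined",
                 class = "kinoflex_stats_error")
  }
  sens <- mean(y_pred[y_true == "active"] == "active")
  spec <- mean(y_pred[y_true == "inactive"] == "inactive")
  (sens + spec) / 2
}
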