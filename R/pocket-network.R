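#' Merge and split count matrices from a pocket event log
#'
#' Counts every recorded merge event into the ordered-pair matrix
#' \eqn{\alpha} and every split event into \eqn{\beta}: `alpha[i, j]` is
#' the number of merge events recorded as `(i, j)`. Counts are preserved
#' exactly as recorded, so the matrices may be asymmetric.
#'
#' @param log A `pocket_event_log`.
#' @return A list of class `merge_split_matrices` with integer matrices
#'   `alpha` (merges) and `beta` (splits), zero on the diagonal.
#' @export
events_to_matrices <- function(log) {
  stopifnot(inherits(log, "pocket_event_log"))
  pn <- log$pocket_names
  count_mat <- function(ev) {
    M <- matrix(0L, length(pn), length(pn), dimnames = list(pn, pn))
    if (nrow(ev)) {
      tab <- table(factor(ev$from, levels = pn), factor(ev$to, levels = pn))
      M <- matrix(as.integer(tab), length(pn), length(pn), dimnames = list(pn, pn))
    }
    M
  }
  structure(list(alpha = count_mat(log$merges), beta = count_mat(log$splits)),
            class = "merge_split_matrices")
}

#' Connection matrix from merge/split counts
#'
#' Symmetrises the merge matrix \eqn{\alpha} and the split matrix
#' \eqn{\beta} by averaging each with its transpose, then averages the two:
#' \deqn{\gamma = \tfrac12\left(\tfrac{\alpha + \alpha^T}{2} +
#'   \tfrac{\beta + \beta^T}{2}\right).}
#' The result is symmetric with zero diagonal, and conserves total events:
#' `sum(gamma) = (sum(alpha) + sum(beta)) / 2`.
#'
#' @param ms A `merge_split_matrices` object (or a list with `alpha` and
#'   `beta` matrices of matching shape).
#' @param per_ns Optional: divide by the trajectory length in nanoseconds
#'   to compare runs of different lengths. Default `NULL` (raw counts).
#' @return A symmetric matrix of class `connection_matrix`.
#' @export
#' @examples
#' ms <- list(alpha = matrix(c(0, 2, 4, 0), 2, 2, byrow = TRUE),
#'            beta  = matrix(c(0, 1, 3, 0), 2, 2, byrow = TRUE))
#' connection_matrix(ms) # off-diagonal 2.5
connection_matrix <- function(ms, per_ns = NULL) {
  alpha <- as.matrix(ms$alpha); beta <- as.matrix(ms$beta)
  if (!all(dim(alpha) == dim(beta))) {
    stop_field("ms", "alpha and beta must have matching shapes")
  }
  sym <- function(M) (M + t(M)) / 2
  gamma <- (sym(alpha) + sym(beta)) / 2
  if (!is.null(per_ns)) {
    check_scalar_number(per_ns, "per_ns", min = 0, strict_min = TRUE)
    gamma <- gamma / per_ns
  }
  structure(gamma, class = c("connection_matrix", "matrix", "array"))
}

#' Time-averaged pocket volumes and detection fractions
#'
#' The average is taken over all frames with undetected frames counted as
#' volume zero, so a pocket that is never detected averages to exactly 0;
#' the detection fraction is the share of frames with positive volume.
#'
#' @param log A `pocket_event_log`.
#' @return A tibble with columns `pocket`, `mean_volume` (cubic angstrom)
#'   and `detection_fraction`.
#' @export
time_averaged_volumes <- function(log) {
  stopifnot(inherits(log, "pocket_event_log"))
  tibble::tibble(
    pocket = log$pocket_names,
    mean_volume = as.numeric(colMeans(log$volumes)),
    detection_fraction = as.numeric(colMeans(log$volumes > 0))
  )
}

#' Pooled per-pocket connection distributions across systems
#'
#' For every pocket, pools the off-diagonal entries of its connection-matrix
#' row across all systems of each activity class ("each row corresponds to a
#' single pocket"), and reduces each system's row to its sum as a scalar
#' connection statistic for group testing. Systems missing a pocket
#' contribute zero rows: absence is data.
#'
#' @param gammas Named list of `connection_matrix` objects, one per system.
#' @param labels Named character vector (`active`/`inactive`), one per
#'   system; names must match `gammas`.
#' @return A list of class `connection_distribution` with tibbles
#'   `entries` (`system, label, pocket, partner, gamma`) and `row_sums`
#'   (`system, label, pocket, connections`).
#' @export
connection_distribution <- function(gammas, labels) {
  if (is.null(names(gammas)) || anyDuplicated(names(gammas))) {
    stop_field("gammas", "must be a uniquely named list of connection matrices")
  }
  labels <- check_labels(labels)
  if (!setequal(names(gammas), names(labels)) && length(labels) != length(gammas)) {
    stop_field("labels", "must supply one label per system")
  }
  if (is.null(names(labels))) names(labels) <- names(gammas)
  pockets <- unique(unlist(lapply(gammas, rownames)))
  if (is.null(pockets)) stop_field("gammas", "connection matrices must carry pocket names")
  entries <- purrr::map_dfr(names(gammas), function(sys) {
    g <- gammas[[sys]]
    full <- matrix(0, length(pockets), length(pockets),
                   dimnames = list(pockets, pockets))
    pn <- rownames(g)
    if (!all(pn %in% pockets)) stop_field("gammas", "inconsistent pocket naming")
    full[pn, pn] <- as.matrix(g)
    purrr::map_dfr(pockets, function(p) {
      partners <- setdiff(pockets, p)
      tibble::tibble(system = sys, label = unname(labels[sys]),
                     pocket = p, partner = partners,
                     gamma = full[p, partners])
    })
  })
  row_sums <- entries |>
    dplyr::group_by(.data$system, .data$label, .data$pocket) |>
    dplyr::summarise(connections = sum(.data$gamma), .groups = "drop")
  structure(list(entries = entries, row_sums = row_sums),
            class = "connection_distribution")
}

#' Write a matrix (alpha, beta or gamma) as CSV with pocket names
#'
#' @param mat A named square matrix.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(mat, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(mat)), rownames = "pocket")
  readr::write_csv(df, path)
  invisible(path)
}

#' Heatmap of a connection matrix
#'
#' @param object A `connection_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot connection_matrix
#' @export
autoplot.connection_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("from", "to", "gamma")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to, fill = .data$gamma)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(gamma)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
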