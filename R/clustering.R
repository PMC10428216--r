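#' Pairwise RMSD matrix over an atom selection
#'
#' Entry (i, j) is the RMSD after least-squares superposition of frame j
#' onto frame i over the selection, so rigid-body motion between frames is
#' removed and the matrix reflects internal (conformational) differences
#' only. By default the superposition fit uses the same selection as the
#' distance (segment fit), isolating, e.g., activation-loop conformation
#' from whole-domain motion; `fit_on = "whole"` fits on all atoms instead.
#'
#' The matrix is symmetric with zero diagonal; the triangle inequality is
#' not guaranteed for superposition RMSD and is not asserted.
#'
#' @param traj A `kinoflex_trajectory`.
#' @param selection Atom selection: `"backbone"`, `"all"`, atom names, atom
#'   indices, or a data frame with `residue_id` and `part`
#'   (`backbone`/`sidechain`/`all`) rows for activation-loop style picks.
#' @param fit_on `"segment"` (default) or `"whole"`: atoms used for the
#'   superposition fit.
#' @return An `n x n` matrix of class `rmsd_matrix` (angstrom).
#' @export
pairwise_rmsd <- function(traj, selection = "backbone",
                          fit_on = c("segment", "whole")) {
  stopifnot(inherits(traj, "kinoflex_trajectory"))
  fit_on <- match.arg(fit_on)
  sel <- select_atoms(traj, selection)
  fit_sel <- if (fit_on == "segment") sel else select_atoms(traj, "all")
  nf <- n_frames(traj)
  # frames restricted to the fit selection; distance measured on `sel`
  sel_in_fit <- match(sel, fit_sel)
  if (anyNA(sel_in_fit)) {
    # distance atoms outside the fit set: fit on union
    fit_sel <- sort(union(fit_sel, sel))
    sel_in_fit <- match(sel, fit_sel)
  }
  frames <- lapply(seq_len(nf), function(i) matrix(traj$coords[i, fit_sel, ], ncol = 3))
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    ref <- frames[[i]]
    for (j in (i + 1L):nf) {
      tr <- kabsch_superpose(frames[[j]], ref)
      fitted <- apply_transform(frames[[j]], tr)
      d <- sqrt(mean(rowSums((fitted[sel_in_fit, , drop = FALSE] -
                                ref[sel_in_fit, , drop = FALSE])^2)))
      D[i, j] <- d; D[j, i] <- d
    }
  }
  structure(D, class = c("rmsd_matrix", "matrix", "array"))
}

#' k-medoids clustering on a precomputed distance matrix
#'
#' Voronoi-iteration k-medoids: medoids are initialised by greedy
#' farthest-point seeding from a seed-chosen first medoid, then assignment
#' (each frame to its nearest medoid) and update (each medoid replaced by
#' the cluster member minimising the within-cluster distance sum) alternate
#' until a fixed point or `max_iter`. The objective — the sum of distances
#' of every frame to its medoid — is non-increasing across iterations.
#' Ties in assignment break toward the medoid with the lower frame index;
#' ties in the medoid update toward the lower frame index.
#'
#' @param D Symmetric distance matrix (e.g. from [pairwise_rmsd()]).
#' @param k Number of clusters (default 10, the convention for
#'   activation-loop ensembles); must be <= the number of frames.
#' @param seed Integer seed choosing the initial medoid.
#' @param max_iter Iteration cap.
#' @return An object of class `kmedoids_clustering`: `k`, `medoids` (frame
#'   indices), `assignment` (cluster index per frame), `objective`,
#'   `cluster_sizes`, `objective_trace` and `iterations`.
#' @export
k_medoids <- function(D, k = 10L, seed = 1L, max_iter = 100L) {
  D <- unclass(as.matrix(D))
  n <- nrow(D)
  if (ncol(D) != n) stop_field("D", "must be square")
  if (max(abs(D - t(D))) > 1e-8) stop_field("D", "must be symmetric")
  k <- check_count(k, "k", min = 1L)
  if (k > n) stop_field("k", "must be <= the number of frames")
  max_iter <- check_count(max_iter, "max_iter", min = 1L)

  medoids <- withr::with_seed(seed, {
    m <- sample.int(n, 1L)
    while (length(m) < k) {
      mind <- apply(D[, m, drop = FALSE], 1, min)
      mind[m] <- -Inf
      # farthest point; which.max ties -> lowest index
      m <- c(m, unname(which.max(mind)))
    }
    sort(m)
  })

  assign_to <- function(medoids) {
    # nearest medoid, ties toward the lower medoid frame index
    sub <- D[, medoids, drop = FALSE]
    unname(apply(sub, 1, which.min))
  }
  objective_of <- function(assignment, medoids) {
    sum(D[cbind(seq_len(n), medoids[assignment])])
  }

  assignment <- assign_to(medoids)
  trace <- objective_of(assignment, medoids)
  for (iter in seq_len(max_iter)) {
    new_medoids <- medoids
    for (c in seq_len(k)) {
      members <- which(assignment == c)
      if (!length(members)) next
      sums <- colSums(D[members, members, drop = FALSE])
      new_medoids[c] <- members[unname(which.min(sums))]
    }
    ord <- order(new_medoids)
    new_medoids <- new_medoids[ord]
    new_assignment <- assign_to(new_medoids)
    obj <- objective_of(new_assignment, new_medoids)
    trace <- c(trace, obj)
    converged <- identical(new_medoids, medoids) &&
      identical(new_assignment, assignment)
    medoids <- new_medoids
    assignment <- new_assignment
    if (converged) break
  }
  structure(
    list(k = k, medoids = medoids, assignment = assignment,
         objective = objective_of(assignment, medoids),
         cluster_sizes = tabulate(assignment, nbins = k),
         objective_trace = trace, iterations = length(trace) - 1L, seed = seed),
    class = "kmedoids_clustering"
  )
}

#' @export
print.kmedoids_clustering <- function(x, ...) {
  cat(sprintf("<kmedoids_clustering> k = %d, objective = %.4f, %d iterations\n",
              x$k, x$objective, x$iterations))
  cat("  sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname k_medoids
#' @param x A `kmedoids_clustering`.
#' @param ... Unused.
#' @method tidy kmedoids_clustering
#' @export
tidy.kmedoids_clustering <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$assignment), cluster = x$assignment,
                 medoid_frame = x$medoids[x$assignment],
                 is_medoid = seq_along(x$assignment) %in% x$medoids)
}

#' @rdname k_medoids
#' @method glance kmedoids_clustering
#' @export
glance.kmedoids_clustering <- function(x, ...) {
  tibble::tibble(k = x$k, objective = x$objective, iterations = x$iterations,
                 n = length(x$assignment),
                 min_cluster = min(x$cluster_sizes), max_cluster = max(x$cluster_sizes))
}

#' Cluster transition graph
#'
#' Counts consecutive-frame cluster changes as undirected edge weights and
#' annotates each cluster with its cardinality and, if a per-frame activity
#' series is given, the mean activity of its member frames. Edge weights
#' plus the number of non-transitions (persistences) always sum to
#' `n - 1`.
#'
#' @param assignment Integer cluster assignment per frame (e.g. from
#'   [k_medoids()]).
#' @param activity Optional per-frame activity probabilities in `[0, 1]`,
#'   same length as `assignment`.
#' @return An object of class `transition_graph`: tibbles `nodes`
#'   (`cluster`, `size`, `mean_activity`) and `edges` (`from`, `to`,
#'   `weight`, with `from < to`), plus `persistence` (count of
#'   non-transitions).
#' @export
transition_graph <- function(assignment, activity = NULL) {
  assignment <- as.integer(assignment)
  n <- length(assignment)
  if (!is.null(activity)) {
    if (length(activity) != n) {
      stop_field("activity", "length must equal the assignment length")
    }
    check_prob(activity, "activity")
  }
  clusters <- sort(unique(assignment))
  nodes <- tibble::tibble(
    cluster = clusters,
    size = vapply(clusters, function(c) sum(assignment == c), 0L),
    mean_activity = if (is.null(activity)) NA_real_ else
      vapply(clusters, function(c) mean(activity[assignment == c]), 0)
  )
  a <- assignment[-n]; b <- assignment[-1]
  moved <- a != b
  persistence <- sum(!moved)
  if (any(moved)) {
    lo <- pmin(a[moved], b[moved]); hi <- pmax(a[moved], b[moved])
    edges <- tibble::tibble(from = lo, to = hi) |>
      dplyr::count(.data$from, .data$to, name = "weight") |>
      dplyr::arrange(.data$from, .data$to)
  } else {
    edges <- tibble::tibble(from = integer(), to = integer(), weight = integer())
  }
  structure(list(nodes = nodes, edges = edges, persistence = persistence,
                 n_frames = n),
            class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("<transition_graph> %d clusters, %d edges, %d persistences over %d frames\n",
              nrow(x$nodes), nrow(x$edges), x$persistence, x$n_frames))
  invisible(x)
}

#' Plot a cluster transition graph
#'
#' Nodes are placed on a circle, sized by cluster cardinality and coloured
#' by mean activity; edge width encodes the interconversion count.
#'
#' @param object A `transition_graph`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot transition_graph
#' @export
autoplot.transition_graph <- function(object, ...) {
  nodes <- object$nodes
  m <- nrow(nodes)
  theta <- 2 * pi * (seq_len(m) - 1) / m
  nodes$x <- cos(theta); nodes$y <- sin(theta)
  p <- ggplot2::ggplot()
  if (nrow(object$edges)) {
    ed <- object$edges
    ed$x <- nodes$x[match(ed$from, nodes$cluster)]
    ed$y <- nodes$y[match(ed$from, nodes$cluster)]
    ed$xend <- nodes$x[match(ed$to, nodes$cluster)]
    ed$yend <- nodes$y[match(ed$to, nodes$cluster)]
    p <- p + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
                   linewidth = .data$weight), colour = "grey60")
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, size = .data$size,
                                     colour = .data$mean_activity)) +
    ggplot2::scale_colour_viridis_c(name = "Mean activity", na.value = "grey30") +
    ggplot2::scale_size_area(name = "Frames") +
    ggplot2::scale_linewidth(name = "Transitions", range = c(0.3, 2)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
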