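#' Per-residue root-mean-square fluctuation
#'
#' Computes backbone RMSF after discarding an equilibration prefix. The
#' fitting protocol is iterative superposition onto the mean structure:
#' every retained frame is superposed onto the first retained frame over
#' the selection, the mean structure is computed, frames are re-fitted onto
#' that mean, and the fit/mean refinement repeats until the per-residue
#' RMSF changes by less than `tol` (usually 2-3 passes); fluctuations are
#' then measured about the converged mean. Per-atom RMSF is
#' \eqn{\sqrt{\langle |r - \bar r|^2 \rangle}}; per-residue RMSF is the
#' root-mean-square of the residue's selected atoms.
#'
#' The discard prefix models equilibration time: by default the first
#' 500 ns are dropped when frame times are present, otherwise the first
#' sixth of the frames.
#'
#' @param traj A `kinoflex_trajectory`.
#' @param selection Atom selection (see details in [pairwise_rmsd()]);
#'   default `"backbone"` (atoms named N, CA, C, O).
#' @param discard_frames Number of leading frames to discard; overrides
#'   `discard_ns`.
#' @param discard_ns Equilibration time to discard in nanoseconds (requires
#'   frame times); default 500 when times exist.
#' @param tol Convergence tolerance (angstrom) on the per-residue RMSF
#'   between successive mean-structure refinements.
#' @param max_refine Cap on refinement passes.
#' @return A tibble of class `rmsf_profile` with columns `residue_id` and
#'   `rmsf` (angstrom), and attributes `n_frames_used` and
#'   `discard_frames`.
#' @export
#' @examples
#' traj <- gen_trajectory(trajectory_spec(helix_residues(6, sigma = 0.3),
#'                                        n_frames = 400, seed = 2))
#' compute_rmsf(traj, discard_frames = 0)
compute_rmsf <- function(traj, selection = "backbone",
                         discard_frames = NULL, discard_ns = NULL,
                         tol = 1e-8, max_refine = 10L) {
  stopifnot(inherits(traj, "kinoflex_trajectory"))
  nf <- n_frames(traj)
  if (is.null(discard_frames)) {
    if (!is.null(traj$frame_times_ns)) {
      cut_ns <- if (is.null(discard_ns)) 500 else discard_ns
      discard_frames <- sum(traj$frame_times_ns < traj$frame_times_ns[1] + cut_ns)
      if (cut_ns == 0) discard_frames <- 0L
    } else if (!is.null(discard_ns)) {
      stop_field("discard_ns", "trajectory has no frame times; use discard_frames")
    } else {
      discard_frames <- floor(nf / 6)
    }
  }
  discard_frames <- check_count(discard_frames, "discard_frames", min = 0L)
  if (nf - discard_frames < 2L) {
    stop_field("discard_frames", "fewer than 2 frames remain after discard")
  }
  sel <- select_atoms(traj, selection)
  keep <- (discard_frames + 1L):nf
  X <- traj$coords[keep, sel, , drop = FALSE]
  m <- length(keep); natoms <- length(sel)

  fit_all <- function(X, ref) {
    out <- array(0, dim(X))
    for (i in seq_len(dim(X)[1])) {
      fr <- matrix(X[i, , ], ncol = 3)
      tr <- kabsch_superpose(fr, ref)
      out[i, , ] <- apply_transform(fr, tr)
    }
    out
  }
  res_ids <- traj$atom_meta$residue_id[sel]
  rmsf_about_mean <- function(fitted) {
    mu <- apply(fitted, c(2, 3), mean)
    disp2 <- (fitted - array(rep(mu, each = m), dim(fitted)))^2
    sqrt(apply(disp2, 2, sum) / m)   # sums x,y,z and frames
  }

  # iterative superposition: fit to frame 1, then repeatedly to the mean
  ref <- matrix(X[1, , ], ncol = 3)
  prev <- NULL
  for (pass in seq_len(max_refine)) {
    fitted <- fit_all(X, ref)
    atom_rmsf <- rmsf_about_mean(fitted)
    res_rmsf <- sqrt(tapply(atom_rmsf^2, res_ids, mean))
    if (!is.null(prev) && max(abs(res_rmsf - prev)) < tol) break
    prev <- res_rmsf
    ref <- apply(fitted, c(2, 3), mean)
  }

  msf_by_res <- tapply(atom_rmsf^2, res_ids, mean)
  out <- tibble::tibble(
    residue_id = as.integer(names(msf_by_res)),
    rmsf = as.numeric(sqrt(msf_by_res))
  )
  out <- out[order(out$residue_id), ]
  structure(out, class = c("rmsf_profile", class(out)),
            n_frames_used = m, discard_frames = discard_frames)
}

#' Write / read an RMSF profile as CSV
#'
#' The on-disk dialect is two columns, `residue_id` and `rmsf_A`.
#'
#' @param profile An `rmsf_profile` (or any data frame with `residue_id`
#'   and `rmsf`).
#' @param path CSV path.
#' @return `path` invisibly (writer); an `rmsf_profile` tibble (reader).
#' @export
write_rmsf_csv <- function(profile, path) {
  readr::write_csv(tibble::tibble(residue_id = profile$residue_id,
                                  rmsf_A = profile$rmsf), path)
  invisible(path)
}

#' @rdname write_rmsf_csv
#' @export
read_rmsf_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("residue_id", "rmsf_A") %in% names(tab))) {
    stop_field("path", "CSV must have columns residue_id, rmsf_A")
  }
  out <- tibble::tibble(residue_id = as.integer(tab$residue_id), rmsf = tab$rmsf_A)
  structure(out, class = c("rmsf_profile", class(out)))
}

#' Plot an RMSF profile
#'
#' @param object An `rmsf_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rmsf_profile
#' @export
autoplot.rmsf_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue_id, y = .data$rmsf)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}
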