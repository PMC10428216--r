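#' Specification for a synthetic Gaussian trajectory
#'
#' Describes a toy molecular ensemble in which every atom fluctuates
#' isotropically (independent Gaussian noise on each Cartesian coordinate)
#' around a fixed mean position. The model is deliberately minimal: an
#' isotropic Gaussian atom has a closed-form root-mean-square fluctuation of
#' \eqn{\sigma\sqrt{3}}, which makes every downstream fluctuation computation
#' testable against an exact value.
#'
#' @param residues Data frame with one row per residue and columns
#'   `residue_id` (unique, strictly increasing integers), `sigma`
#'   (per-coordinate fluctuation standard deviation, in angstrom, >= 0) and
#'   `x`, `y`, `z` (mean position of the residue, in angstrom).
#' @param n_frames Number of frames to generate (>= 1).
#' @param backbone_atoms_per_residue Number of backbone atoms written per
#'   residue (1 to 4, named from N, CA, C, O). Default 4.
#' @param frame_spacing_ns Optional spacing between frames in nanoseconds;
#'   when set, generated trajectories carry frame times.
#' @param seed Integer seed making generation fully reproducible.
#'
#' @return An object of class `trajectory_spec`.
#' @seealso [gen_trajectory()]
#' @export
#' @examples
#' sp <- trajectory_spec(helix_residues(5, sigma = 0.5), n_frames = 100, seed = 1)
#' traj <- gen_trajectory(sp)
trajectory_spec <- function(residues, n_frames, backbone_atoms_per_residue = 4L,
                            frame_spacing_ns = NULL, seed = 1L) {
  if (!is.data.frame(residues) || nrow(residues) == 0) {
    stop_field("residues", "must be a non-empty data frame")
  }
  needed <- c("residue_id", "sigma", "x", "y", "z")
  missing <- setdiff(needed, names(residues))
  if (length(missing)) {
    stop_field("residues", paste("missing columns:", paste(missing, collapse = ", ")))
  }
  ids <- residues$residue_id
  if (anyDuplicated(ids) || any(diff(ids) <= 0)) {
    stop_field("residues$residue_id", "must be unique and strictly increasing")
  }
  if (any(!is.finite(residues$sigma)) || any(residues$sigma < 0)) {
    stop_field("residues$sigma", "must be finite and >= 0")
  }
  n_frames <- check_count(n_frames, "n_frames", min = 1L)
  backbone_atoms_per_residue <- check_count(backbone_atoms_per_residue,
                                            "backbone_atoms_per_residue", min = 1L)
  if (backbone_atoms_per_residue > 4L) {
    stop_field("backbone_atoms_per_residue", "at most 4 (N, CA, C, O)")
  }
  if (!is.null(frame_spacing_ns)) {
    check_scalar_number(frame_spacing_ns, "frame_spacing_ns", min = 0, strict_min = TRUE)
  }
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(residues = tibble::as_tibble(residues[needed]),
         n_frames = n_frames,
         backbone_atoms_per_residue = backbone_atoms_per_residue,
         frame_spacing_ns = frame_spacing_ns,
         seed = seed),
    class = "trajectory_spec"
  )
}

#' Residue layout along an ideal helix
#'
#' Convenience builder for [trajectory_spec()]: places `n` residues along an
#' alpha-helical curve (rise 1.5 A, 100 degrees per residue, radius 2.3 A) so
#' that mean structures are never collinear and rigid-body fitting is well
#' conditioned.
#'
#' @param n Number of residues.
#' @param sigma Per-coordinate fluctuation sd in angstrom; recycled to `n`.
#' @param start_id First residue id.
#' @return Tibble suitable as the `residues` argument of [trajectory_spec()].
#' @export
helix_residues <- function(n, sigma = 0.5, start_id = 1L) {
  n <- check_count(n, "n", min = 1L)
  theta <- (seq_len(n) - 1) * 100 * pi / 180
  tibble::tibble(
    residue_id = start_id + seq_len(n) - 1L,
    sigma = rep_len(sigma, n),
    x = 2.3 * cos(theta),
    y = 2.3 * sin(theta),
    z = 1.5 * (seq_len(n) - 1)
  )
}

#' Specification for a synthetic fluctuation panel
#'
#' Describes a kinase panel (rows) by alignment-column (columns) RMSF matrix
#' in which one planted column carries the activity signal: active kinases
#' draw low values and inactive kinases high values, encoding the observation
#' that inactive kinases are the more flexible class. An optional correlated
#' block mimics neighbouring activation-segment residues whose fluctuations
#' track the signal residue.
#'
#' All RMSF draws are truncated below at zero (a fluctuation cannot be
#' negative).
#'
#' @param n_active,n_inactive Class sizes; their sum must be >= 4.
#' @param n_columns Number of alignment columns.
#' @param signal_column Index of the planted signal column.
#' @param mu_active,mu_inactive Class means of the signal column (angstrom);
#'   `mu_inactive > mu_active` is required.
#' @param sigma_within Within-class sd of the signal column (angstrom).
#' @param background_mu,background_sigma Mean and sd of uninformative columns.
#' @param corr_block Integer indices of columns correlated with the signal
#'   column (may be empty). The defaults sit just above the signal column:
#'   within the correlated group the signal keeps the lowest index, so the
#'   deterministic lowest-index tie-break of [fit_stump()] cannot hand a
#'   Gini tie to a backup column.
#' @param rho Correlation coefficient in `[0, 1]` between the signal column
#'   and each `corr_block` column.
#' @param seed Integer seed.
#' @return An object of class `panel_spec`.
#' @seealso [gen_fluctuation_panel()]
#' @export
panel_spec <- function(n_active = 19L, n_inactive = 24L, n_columns = 223L,
                       signal_column = 120L, mu_active = 0.6, mu_inactive = 1.3,
                       sigma_within = 0.18, background_mu = 0.8,
                       background_sigma = 0.25,
                       corr_block = c(121L, 122L), rho = 0.95, seed = 1L) {
  n_active <- check_count(n_active, "n_active", min = 0L)
  n_inactive <- check_count(n_inactive, "n_inactive", min = 0L)
  if (n_active + n_inactive < 4L) {
    stop_field("n_active + n_inactive", "panel too small to split (need >= 4 rows)")
  }
  n_columns <- check_count(n_columns, "n_columns", min = 1L)
  signal_column <- check_count(signal_column, "signal_column", min = 1L)
  if (signal_column > n_columns) stop_field("signal_column", "must be <= n_columns")
  check_scalar_number(mu_active, "mu_active", min = 0)
  check_scalar_number(mu_inactive, "mu_inactive", min = 0)
  if (mu_inactive < mu_active) {
    stop_field("mu_inactive", "must be >= mu_active (inactive kinases are the more flexible class); equality yields a null, signal-free panel")
  }
  check_scalar_number(sigma_within, "sigma_within", min = 0)
  check_scalar_number(background_mu, "background_mu", min = 0)
  check_scalar_number(background_sigma, "background_sigma", min = 0)
  if (length(corr_block)) {
    corr_block <- vapply(corr_block, check_count, integer(1), field = "corr_block")
    if (any(corr_block > n_columns)) stop_field("corr_block", "indices must be <= n_columns")
    if (signal_column %in% corr_block) stop_field("corr_block", "must not contain signal_column")
    if (anyDuplicated(corr_block)) stop_field("corr_block", "indices must be unique")
  } else {
    corr_block <- integer(0)
  }
  check_prob(rho, "rho")
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(n_active = n_active, n_inactive = n_inactive, n_columns = n_columns,
         signal_column = signal_column, mu_active = mu_active,
         mu_inactive = mu_inactive, sigma_within = sigma_within,
         background_mu = background_mu, background_sigma = background_sigma,
         corr_block = as.integer(corr_block), rho = rho, seed = seed),
    class = "panel_spec"
  )
}

#' Specification for a synthetic pocket event stream
#'
#' Emulates the per-frame output of a trajectory pocket tracker: each pocket
#' is detected in a frame with some probability, carries a lognormal volume
#' when detected (zero when absent), and ordered pocket pairs exchange
#' Poisson-distributed merge and split events.
#'
#' `volume_mu` is the median (geometric mean) volume in cubic angstrom and
#' `volume_sigma` the lognormal shape parameter on the log scale, so
#' `volume_sigma = 0` degenerates to a constant volume of exactly
#' `volume_mu`.
#'
#' @param pocket_names Pocket labels. Defaults to the seven-pocket tyrosine
#'   kinase set: the ATP site plus six allosteric sites (AAS, CMP, DRS, PDIG,
#'   PIF, MPP).
#' @param n_frames Number of frames.
#' @param volume_mu,volume_sigma Per-pocket lognormal volume parameters;
#'   recycled to the number of pockets.
#' @param presence_prob Per-pocket per-frame detection probability in
#'   `[0, 1]`; recycled.
#' @param link_rate Expected merge events (and, independently, split events)
#'   per ordered pocket pair per frame. Either a scalar or a full
#'   `n_pockets x n_pockets` matrix; the diagonal is ignored.
#' @param frame_spacing_ps Time between frames in picoseconds (default 100).
#' @param seed Integer seed.
#' @return An object of class `pocket_sim_spec`.
#' @seealso [gen_pocket_events()]
#' @export
pocket_sim_spec <- function(pocket_names = c("ATP", "AAS", "CMP", "DRS", "PDIG", "PIF", "MPP"),
                            n_frames = 1000L,
                            volume_mu = c(550, 150, 250, 200, 180, 220, 160),
                            volume_sigma = 0.45,
                            presence_prob = c(1, 0.6, 0.8, 0.75, 0.7, 0.8, 0.65),
                            link_rate = 0.002,
                            frame_spacing_ps = 100,
                            seed = 1L) {
  pocket_names <- as.character(pocket_names)
  if (length(pocket_names) < 1L || anyDuplicated(pocket_names)) {
    stop_field("pocket_names", "must be non-empty and unique")
  }
  np <- length(pocket_names)
  n_frames <- check_count(n_frames, "n_frames", min = 1L)
  volume_mu <- rep_len(volume_mu, np)
  volume_sigma <- rep_len(volume_sigma, np)
  if (any(!is.finite(volume_mu)) || any(volume_mu <= 0)) {
    stop_field("volume_mu", "volumes must be > 0 when present")
  }
  if (any(!is.finite(volume_sigma)) || any(volume_sigma < 0)) {
    stop_field("volume_sigma", "must be >= 0")
  }
  presence_prob <- check_prob(rep_len(presence_prob, np), "presence_prob")
  if (is.matrix(link_rate)) {
    if (!all(dim(link_rate) == np)) stop_field("link_rate", "matrix must be n_pockets x n_pockets")
  } else {
    check_scalar_number(link_rate, "link_rate", min = 0)
    link_rate <- matrix(link_rate, np, np)
  }
  if (any(!is.finite(link_rate)) || any(link_rate < 0)) {
    stop_field("link_rate", "rates must be >= 0")
  }
  diag(link_rate) <- 0
  dimnames(link_rate) <- list(pocket_names, pocket_names)
  check_scalar_number(frame_spacing_ps, "frame_spacing_ps", min = 0, strict_min = TRUE)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(pocket_names = pocket_names, n_frames = n_frames,
         volume_mu = volume_mu, volume_sigma = volume_sigma,
         presence_prob = presence_prob, link_rate = link_rate,
         frame_spacing_ps = frame_spacing_ps, seed = seed),
    class = "pocket_sim_spec"
  )
}
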