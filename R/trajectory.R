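#' Trajectory container
#'
#' A lightweight in-memory trajectory: a `frames x atoms x 3` coordinate
#' array (angstrom) plus per-atom metadata. All fluctuation and clustering
#' functions in the package consume this object.
#'
#' @param coords Numeric array of dimension `frames x atoms x 3`.
#' @param atom_meta Data frame with one row per atom and columns
#'   `residue_id`, `residue_name`, `atom_name`, `is_backbone`.
#' @param frame_times_ns Optional numeric vector of frame times in
#'   nanoseconds (length = number of frames).
#' @return An object of class `kinoflex_trajectory`.
#' @export
new_trajectory <- function(coords, atom_meta, frame_times_ns = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop_field("coords", "must be a frames x atoms x 3 array")
  }
  if (dim(coords)[1] < 1L) stop_field("coords", "need at least one frame")
  atom_meta <- tibble::as_tibble(atom_meta)
  needed <- c("residue_id", "residue_name", "atom_name", "is_backbone")
  missing <- setdiff(needed, names(atom_meta))
  if (length(missing)) {
    stop_field("atom_meta", paste("missing columns:", paste(missing, collapse = ", ")))
  }
  if (nrow(atom_meta) != dim(coords)[2]) {
    stop_field("atom_meta", "row count must match the number of atoms in coords")
  }
  if (!is.null(frame_times_ns) && length(frame_times_ns) != dim(coords)[1]) {
    stop_field("frame_times_ns", "length must equal the number of frames")
  }
  structure(
    list(coords = coords, atom_meta = atom_meta, frame_times_ns = frame_times_ns),
    class = "kinoflex_trajectory"
  )
}

#' @export
print.kinoflex_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<kinoflex_trajectory> %d frames x %d atoms (%d residues)%s\n",
              d[1], d[2], length(unique(x$atom_meta$residue_id)),
              if (is.null(x$frame_times_ns)) "" else ", timed"))
  invisible(x)
}

#' @export
dim.kinoflex_trajectory <- function(x) dim(x$coords)

n_frames <- function(traj) dim(traj$coords)[1]

# Backbone atom names in their conventional intra-residue order, with fixed
# local offsets (angstrom) so atoms within a residue are geometrically
# distinct even when the residue mean collapses to a point.
.backbone_atoms <- c("N", "CA", "C", "O")
.backbone_offsets <- matrix(c(-0.75, 0.35, 0,
                              0, 0, 0,
                              0.75, 0.35, 0,
                              1.1, 1.5, 0.3),
                            nrow = 4, byrow = TRUE,
                            dimnames = list(.backbone_atoms, c("x", "y", "z")))

#' Generate a synthetic Gaussian trajectory
#'
#' Every atom's coordinates are drawn i.i.d. per frame from an isotropic
#' Gaussian centred on the atom's mean position with the per-coordinate
#' standard deviation of its residue. Generation is fully deterministic
#' given the spec's seed. The theoretical RMSF of such an atom is
#' \eqn{\sigma\sqrt{3}}.
#'
#' @param spec A [trajectory_spec()].
#' @return A [new_trajectory()] object.
#' @export
#' @examples
#' traj <- gen_trajectory(trajectory_spec(helix_residues(4), n_frames = 50, seed = 7))
#' dim(traj)
gen_trajectory <- function(spec) {
  if (!inherits(spec, "trajectory_spec")) stop_field("spec", "must be a trajectory_spec")
  res <- spec$residues
  napr <- spec$backbone_atoms_per_residue
  atom_names <- .backbone_atoms[seq_len(napr)]
  nres <- nrow(res)
  natoms <- nres * napr

  atom_meta <- tibble::tibble(
    residue_id = rep(res$residue_id, each = napr),
    residue_name = "ALA",
    atom_name = rep(atom_names, times = nres),
    is_backbone = TRUE
  )

  base <- matrix(0, natoms, 3)
  for (a in seq_len(napr)) {
    idx <- seq(a, natoms, by = napr)
    base[idx, ] <- cbind(res$x, res$y, res$z) +
      matrix(.backbone_offsets[a, ], nres, 3, byrow = TRUE)
  }
  sigma_atom <- rep(res$sigma, each = napr)

  nf <- spec$n_frames
  coords <- withr::with_seed(spec$seed, {
    noise <- array(rnorm(nf * natoms * 3L), dim = c(nf, natoms, 3L))
    out <- array(0, dim = c(nf, natoms, 3L))
    for (k in 1:3) {
      out[, , k] <- matrix(base[, k], nf, natoms, byrow = TRUE) +
        noise[, , k] * matrix(sigma_atom, nf, natoms, byrow = TRUE)
    }
    out
  })

  times <- if (!is.null(spec$frame_spacing_ns)) (seq_len(nf) - 1) * spec$frame_spacing_ns
  new_trajectory(coords, atom_meta, frame_times_ns = times)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Each frame is written as one `MODEL`/`ENDMDL` block. Coordinates are
#' written at PDB precision (three decimals, i.e. milliangstrom).
#'
#' @param traj A `kinoflex_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "kinoflex_trajectory"))
  d <- dim(traj$coords)
  # bio3d expects frames x (x1,y1,z1,x2,...) layout
  xyz <- matrix(aperm(traj$coords, c(1, 3, 2)), nrow = d[1])
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = traj$atom_meta$residue_id,
                   resid = traj$atom_meta$residue_name,
                   elety = traj$atom_meta$atom_name)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' @param path PDB file with one or more `MODEL` blocks.
#' @param backbone_atoms Atom names flagged as backbone (default N, CA, C, O).
#' @return A `kinoflex_trajectory`.
#' @export
read_trajectory_pdb <- function(path, backbone_atoms = .backbone_atoms) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  natoms <- ncol(xyz) / 3L
  nf <- nrow(xyz)
  coords <- array(0, dim = c(nf, natoms, 3L))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, by = 3L, length.out = natoms), drop = FALSE]
  atom_meta <- tibble::tibble(
    residue_id = as.integer(pdb$atom$resno),
    residue_name = pdb$atom$resid,
    atom_name = pdb$atom$elety,
    is_backbone = pdb$atom$elety %in% backbone_atoms
  )
  new_trajectory(coords, atom_meta)
}

#' Read a plain per-frame coordinate table as a trajectory
#'
#' Expects a CSV with columns `frame, atom_index, x, y, z` (coordinates in
#' angstrom); atom metadata is supplied separately since the flat table
#' carries none.
#'
#' @param path CSV file path.
#' @param atom_meta Per-atom metadata data frame (see [new_trajectory()]).
#' @return A `kinoflex_trajectory`.
#' @export
read_trajectory_csv <- function(path, atom_meta) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("frame", "atom_index", "x", "y", "z")
  if (!all(needed %in% names(tab))) {
    stop_field("path", "CSV must have columns frame, atom_index, x, y, z")
  }
  frames <- sort(unique(tab$frame))
  atoms <- sort(unique(tab$atom_index))
  coords <- array(NA_real_, dim = c(length(frames), length(atoms), 3L))
  fi <- match(tab$frame, frames)
  ai <- match(tab$atom_index, atoms)
  coords[cbind(fi, ai, 1L)] <- tab$x
  coords[cbind(fi, ai, 2L)] <- tab$y
  coords[cbind(fi, ai, 3L)] <- tab$z
  if (anyNA(coords)) stop_field("path", "coordinate table has missing (frame, atom) entries")
  new_trajectory(coords, atom_meta)
}

#' Write a trajectory as a flat coordinate CSV
#'
#' @param traj A `kinoflex_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  d <- dim(traj$coords)
  tab <- tibble::tibble(
    frame = rep(seq_len(d[1]), each = d[2]),
    atom_index = rep(seq_len(d[2]), times = d[1]),
    x = as.vector(t(traj$coords[, , 1])),
    y = as.vector(t(traj$coords[, , 2])),
    z = as.vector(t(traj$coords[, , 3]))
  )
  readr::write_csv(tab, path)
  invisible(path)
}

# Resolve an atom selection to integer atom indices.
# Accepts: "backbone" / "all"; a character vector of atom names; an integer
# vector of atom indices; or a data frame with columns residue_id and part
# ("backbone", "sidechain" or "all") for activation-loop style selections.
select_atoms <- function(traj, selection) {
  meta <- traj$atom_meta
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1L | idx > nrow(meta))) stop_field("selection", "atom index out of range")
    return(idx)
  }
  if (is.character(selection) && length(selection) == 1L && selection %in% c("backbone", "all")) {
    idx <- if (selection == "backbone") which(meta$is_backbone) else seq_len(nrow(meta))
  } else if (is.character(selection)) {
    idx <- which(meta$atom_name %in% selection)
  } else if (is.data.frame(selection)) {
    if (!all(c("residue_id", "part") %in% names(selection))) {
      stop_field("selection", "data-frame selection needs columns residue_id, part")
    }
    idx <- integer(0)
    for (i in seq_len(nrow(selection))) {
      in_res <- meta$residue_id == selection$residue_id[i]
      part <- selection$part[i]
      keep <- switch(part,
                     backbone = in_res & meta$is_backbone,
                     sidechain = in_res & !meta$is_backbone,
                     all = in_res,
                     stop_field("selection$part", "must be backbone, sidechain or all"))
      idx <- c(idx, which(keep))
    }
    idx <- sort(unique(idx))
  } else {
    stop_field("selection", "unsupported selection type")
  }
  if (length(idx) == 0L) stop_field("selection", "selects no atoms")
  idx
}
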