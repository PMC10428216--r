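#' Least-squares rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between the
#' masked atoms of `mobile` and `reference`. The returned transform maps
#' mobile coordinates (row vectors) as `fitted = mobile %*% rotation +
#' translation`, i.e. `apply_transform(mobile, fit)`.
#'
#' @param mobile,reference Numeric `atoms x 3` coordinate matrices (angstrom).
#' @param mask Atom indices (into the rows of both matrices) used for the
#'   fit; default all atoms. At least three non-collinear atoms are required.
#' @return A list of class `rigid_transform` with elements `rotation`
#'   (3 x 3, determinant +1), `translation` (length 3) and `rmsd`
#'   (angstrom, over the mask after fitting).
#' @export
#' @examples
#' ref <- matrix(rnorm(30), 10, 3)
#' fit <- kabsch_superpose(ref, ref)
#' fit$rmsd # 0
kabsch_superpose <- function(mobile, reference, mask = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L) {
    stop_field("mobile/reference", "coordinate matrices must have 3 columns")
  }
  if (is.null(mask)) mask <- seq_len(nrow(mobile))
  if (length(mask) < 3L) {
    rlang::abort("superposition mask must select at least 3 atoms",
                 class = "kinoflex_geometry_error")
  }
  A <- mobile[mask, , drop = FALSE]
  B <- reference[mask, , drop = FALSE]
  if (nrow(A) != nrow(B)) {
    stop_field("mask", "mask must resolve to the same atoms in both frames")
  }
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinear (or degenerate) masks leave the rotation underdetermined
  sv_a <- svd(A0, nu = 0, nv = 0)$d
  if (sv_a[2] <= 1e-8 * max(sv_a[1], 1)) {
    rlang::abort("superposition mask is collinear: rotation is underdetermined",
                 class = "kinoflex_geometry_error")
  }
  H <- crossprod(A0, B0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  translation <- cb - as.vector(ca %*% R)
  fitted <- A %*% R + matrix(translation, nrow(A), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords `atoms x 3` matrix.
#' @param transform A `rigid_transform` from [kabsch_superpose()].
#' @return Transformed `atoms x 3` matrix.
#' @export
apply_transform <- function(coords, transform) {
  coords %*% transform$rotation +
    matrix(transform$translation, nrow(coords), 3, byrow = TRUE)
}
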