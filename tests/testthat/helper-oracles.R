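# Independent oracles used to cross-check the package's implementations.
# These deliberately use different algorithms / code paths than R/.

# Brute-force decision stump: scalar double loop over every column and every
# midpoint between consecutive distinct sorted values, identical declared
# conventions (weighted Gini, lowest column index then lowest threshold on
# ties, below-side majority class with ties to "active").
oracle_fit_stump <- function(panel, label_col = "label") {
  y <- panel[[label_col]]
  feats <- setdiff(names(panel), c("kinase", label_col))
  feats <- feats[vapply(panel[feats], is.numeric, TRUE)]
  n <- length(y)
  best <- NULL
  for (j in seq_along(feats)) {
    v <- panel[[feats[j]]]
    sv <- sort(unique(v))
    if (length(sv) < 2) next
    for (m in seq_len(length(sv) - 1)) {
      thr <- (sv[m] + sv[m + 1]) / 2
      below <- v < thr
      nL <- sum(below); nR <- n - nL
      aL <- sum(y[below] == "active"); aR <- sum(y == "active") - aL
      gL <- 1 - (aL / nL)^2 - ((nL - aL) / nL)^2
      gR <- 1 - (aR / nR)^2 - ((nR - aR) / nR)^2
      imp <- (nL / n) * gL + (nR / n) * gR
      if (is.null(best) || imp < best$imp) {
        best <- list(imp = imp, column = feats[j], threshold = thr,
                     orientation = if (aL >= nL - aL) "active" else "inactive")
      }
    }
  }
  best
}

# RMSD after optimal superposition via Horn's quaternion method: the minimal
# RMSD is sqrt((G_A + G_B - 2*lambda_max)/n) where lambda_max is the largest
# eigenvalue of the 4x4 key matrix. No SVD, no explicit rotation.
oracle_rmsd_quaternion <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  n <- nrow(A)
  M <- crossprod(A, B)  # Sxy etc., A = mobile, B = reference
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / n
  sqrt(max(msd, 0))
}

# Two-sided Student-t tail probability by numerical quadrature of the
# density, independent of pt().
oracle_t_pvalue <- function(t_stat, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(t_stat), Inf,
                       rel.tol = 1e-12)$value
}

# Per-atom/per-residue RMSF by a literal per-frame loop about the frame mean
# (no superposition): valid comparison when the scaffold is rigid enough or
# superposition is bypassed.
oracle_rmsf_no_fit <- function(coords3d) {
  m <- dim(coords3d)[1]
  mu <- apply(coords3d, c(2, 3), mean)
  acc <- rep(0, dim(coords3d)[2])
  for (i in seq_len(m)) {
    d <- matrix(coords3d[i, , ], ncol = 3) - mu
    acc <- acc + rowSums(d^2)
  }
  sqrt(acc / m)
}

# Two well-separated frame bundles for planted-cluster recovery: bundles of
# frames built by adding small noise to two distant reference structures.
make_two_bundles <- function(seed, n_per = 10L, n_atoms = 8L, noise = 0.05) {
  withr::with_seed(seed, {
    ref1 <- matrix(rnorm(n_atoms * 3), n_atoms, 3)
    ref2 <- ref1 + matrix(rnorm(n_atoms * 3, sd = 4), n_atoms, 3)
    coords <- array(0, dim = c(2L * n_per, n_atoms, 3L))
    for (i in seq_len(n_per)) {
      coords[i, , ] <- ref1 + matrix(rnorm(n_atoms * 3, sd = noise), n_atoms, 3)
      coords[n_per + i, , ] <- ref2 + matrix(rnorm(n_atoms * 3, sd = noise), n_atoms, 3)
    }
    meta <- tibble::tibble(residue_id = seq_len(n_atoms), residue_name = "ALA",
                           atom_name = "CA", is_backbone = TRUE)
    list(traj = new_trajectory(coords, meta),
         truth = rep(1:2, each = n_per))
  })
}

# Small random panel for oracle-equality sweeps.
random_panel <- function(seed, n_rows = NULL, n_cols = NULL) {
  withr::with_seed(seed, {
    if (is.null(n_rows)) n_rows <- sample(6:15, 1)
    if (is.null(n_cols)) n_cols <- sample(2:10, 1)
    labels <- character(0)
    while (length(unique(labels)) < 2) {
      labels <- sample(c("active", "inactive"), n_rows, replace = TRUE)
    }
    M <- matrix(round(stats::rnorm(n_rows * n_cols), 2), n_rows, n_cols)
    colnames(M) <- paste0("c", seq_len(n_cols))
    dplyr::bind_cols(tibble::tibble(kinase = paste0("k", seq_len(n_rows)),
                                    label = labels),
                     tibble::as_tibble(as.data.frame(M)))
  })
}
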