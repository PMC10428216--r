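#' Generate a synthetic fluctuation panel
#'
#' Draws a kinases-by-columns RMSF matrix with a planted single-residue
#' activity signal. The signal column is sampled from class-dependent
#' normals truncated below at zero (active low, inactive high); columns in
#' the correlated block are built as
#' \eqn{\rho z_{signal} + \sqrt{1-\rho^2}\,\varepsilon} on the standardised
#' scale and then rescaled to the background mean and spread; all other
#' columns are uninformative background. Row labels are exactly
#' `n_active` actives followed by `n_inactive` inactives.
#'
#' @param spec A [panel_spec()].
#' @return A tibble of class `fluct_panel` with columns `kinase`, `label`
#'   and one numeric column per alignment column (named `c<k>`). Ground
#'   truth is carried in attributes `signal_column`, `corr_block` (column
#'   names) and `spec`.
#' @export
#' @examples
#' panel <- gen_fluctuation_panel(panel_spec(n_active = 5, n_inactive = 5,
#'                                           n_columns = 20, signal_column = 7,
#'                                           corr_block = c(5L, 6L), seed = 3))
#' dplyr::count(panel, label)
gen_fluctuation_panel <- function(spec) {
  if (!inherits(spec, "panel_spec")) stop_field("spec", "must be a panel_spec")
  n <- spec$n_active + spec$n_inactive
  labels <- c(rep("active", spec$n_active), rep("inactive", spec$n_inactive))

  M <- withr::with_seed(spec$seed, {
    M <- matrix(0, n, spec$n_columns)
    background <- setdiff(seq_len(spec$n_columns),
                          c(spec$signal_column, spec$corr_block))
    for (j in background) {
      M[, j] <- rtruncnorm_lower(n, spec$background_mu, spec$background_sigma)
    }
    mu <- ifelse(labels == "active", spec$mu_active, spec$mu_inactive)
    M[, spec$signal_column] <- rtruncnorm_lower(n, mu, spec$sigma_within)
    if (length(spec$corr_block)) {
      sig <- M[, spec$signal_column]
      s <- stats::sd(sig)
      z <- if (s > 0) (sig - mean(sig)) / s else rep(0, n)
      for (j in spec$corr_block) {
        eps <- rnorm(n)
        raw <- spec$rho * z + sqrt(1 - spec$rho^2) * eps
        M[, j] <- pmax(0, spec$background_mu + spec$background_sigma * raw)
      }
    }
    M
  })

  colnames(M) <- paste0("c", seq_len(spec$n_columns))
  out <- tibble::as_tibble(as.data.frame(M))
  out <- dplyr::bind_cols(
    tibble::tibble(kinase = sprintf("TK%02d-1_%s", seq_len(n),
                                    ifelse(labels == "active", "a", "i")),
                   label = labels),
    out
  )
  structure(out,
            class = c("fluct_panel", class(out)),
            signal_column = paste0("c", spec$signal_column),
            corr_block = paste0("c", spec$corr_block),
            spec = spec)
}

#' Write / read a fluctuation panel as CSV
#'
#' On disk the panel is one row per kinase with a `kinase` id column, a
#' `label` column (`active`/`inactive`) and one numeric column per
#' alignment column.
#'
#' @param panel A `fluct_panel` tibble (or compatible data frame).
#' @param path CSV path.
#' @return `path` invisibly (writer); a `fluct_panel` tibble (reader).
#' @export
write_panel_csv <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("kinase", "label") %in% names(tab))) {
    stop_field("path", "panel CSV must have 'kinase' and 'label' columns")
  }
  tab$label <- check_labels(tab$label, "label")
  structure(tab, class = c("fluct_panel", class(tab)))
}

# Numeric feature columns of a panel (everything except ids/labels).
panel_feature_names <- function(panel) {
  setdiff(names(panel), c("kinase", "label"))
}
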