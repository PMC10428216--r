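# Internal helpers shared across modules.

# Validation error with the offending field named, so callers can see at a
# glance which part of a spec is wrong.
stop_field <- function(field, msg) {
  rlang::abort(sprintf("invalid `%s`: %s", field, msg), class = "kinoflex_validation_error")
}

check_scalar_number <- function(x, field, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  if (strict_min && x <= min) stop_field(field, sprintf("must be > %g", min))
  if (!strict_min && x < min) stop_field(field, sprintf("must be >= %g", min))
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != as.integer(x)) {
    stop_field(field, "must be a single integer")
  }
  if (x < min) stop_field(field, sprintf("must be >= %d", min))
  invisible(as.integer(x))
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_field(field, "must lie in [0, 1]")
  }
  invisible(x)
}

# Labels used throughout: "active" / "inactive" character vectors.
check_labels <- function(labels, field = "labels") {
  labels <- as.character(labels)
  if (any(!labels %in% c("active", "inactive"))) {
    stop_field(field, "labels must be 'active' or 'inactive'")
  }
  labels
}

# Draw from a normal truncated below at `lower` via inverse-CDF sampling:
# exact, vectorised, and deterministic under the current RNG state.
rtruncnorm_lower <- function(n, mean, sd, lower = 0) {
  if (all(sd == 0)) return(rep_len(pmax(mean, lower), n))
  p_lo <- pnorm((lower - mean) / sd)
  u <- runif(n, min = p_lo, max = 1)
  mean + sd * qnorm(u)
}
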