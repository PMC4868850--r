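# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Conventional reporting-style rounding: halves round away from zero
#' (0.265 -> 0.27 at 2 digits), unlike \code{round()}'s round-half-even.
#' Used when quoting FDRs and percentages at printed precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. Each generator draws from its own stream, seeded explicitly.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Normal draws truncated to [lower, upper] by rejection sampling.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}

# Coerce the various expression containers to a numeric matrix on the
# scale the values are stored in.
expr_values <- function(x) {
  if (inherits(x, "norm_mat")) x$values else as.matrix(x)
}

# Linear-scale (non-log) expression values, for fold changes and
# direction calls.
expr_linear <- function(x) {
  if (inherits(x, "norm_mat")) {
    if (isTRUE(x$log_transformed)) 2^x$values - 1 else x$values
  } else {
    as.matrix(x)
  }
}

# Validate a two-level grouping factor aligned with the columns of an
# expression matrix; returns a factor with the stated reference level
# first (contrasts are level 2 minus level 1).
check_groups <- function(groups, n_samples, min_per_group = 1L) {
  groups <- as.factor(groups)
  if (length(groups) != n_samples) {
    stop("'groups' must have one entry per sample column", call. = FALSE)
  }
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L) {
    stop("'groups' must have exactly two levels", call. = FALSE)
  }
  tab <- table(groups)
  if (any(tab < min_per_group)) {
    stop(sprintf("each group needs at least %d samples (got %s)",
                 min_per_group, paste(tab, collapse = "/")), call. = FALSE)
  }
  groups
}
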