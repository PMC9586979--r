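# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from the single top-level seed.
# Every random stage k of the pipeline draws from its own stream so that
# adding or reordering stages never perturbs another stage's draws.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  (abs(as.integer(seed)) * 131L + as.integer(stream) * 7919L) %% 2147483611L
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0)) {
    abort(sprintf("`%s` must be numeric.", name), class = "mangroflux_invalid_input")
  }
  if (any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite.", name), class = "mangroflux_invalid_input")
  }
  if (any(x < lower) || any(x > upper)) {
    abort(sprintf("`%s` must be in [%s, %s].", name, lower, upper),
      class = "mangroflux_invalid_input")
  }
  invisible(x)
}

check_count <- function(x, name) {
  check_number(x, name, lower = 1)
  if (any(x != as.integer(x))) {
    abort(sprintf("`%s` must be a whole number.", name),
      class = "mangroflux_invalid_input")
  }
  invisible(x)
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s", what,
      paste(missing, collapse = ", ")), class = "mangroflux_invalid_input")
  }
  invisible(data)
}

# Positive-truncated normal draws by resampling; deterministic under a seed.
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
  }
  x
}
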