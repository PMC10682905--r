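# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
abort_input <- function(msg, ...) {
  stop(structure(
    list(message = sprintf(msg, ...), call = sys.call(-1)),
    class = c("nichegrad_input_error", "error", "condition")
  ))
}

#' @keywords internal
abort_internal <- function(msg, ...) {
  stop(structure(
    list(message = sprintf(msg, ...), call = sys.call(-1)),
    class = c("nichegrad_internal_error", "error", "condition")
  ))
}

# Evaluate `expr` under a local RNG stream; the caller's RNG state is
# untouched.  All stochastic operations in the package go through this so
# that a single integer seed pins down the whole artifact.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_input("seed must be a single finite number")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Deterministic fan-out of a master seed into per-stage child seeds.
# Kept below 2^31 so the result is always a valid R integer seed.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2047L + as.integer(offset) * 7919L
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Great-circle distance in km (haversine, spherical Earth 6371 km).
# Ellipsoidal error is negligible at the few-km scale thinning operates on.
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}
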