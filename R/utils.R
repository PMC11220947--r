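# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (0.5 -> 1), matching
#' how clinical tables are typically typeset, rather than R's banker's
#' rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.345), 0)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Minutes elapsed from t0; accepts POSIXct or plain numeric (already minutes).
as_minutes <- function(t, t0) {
  if (inherits(t, "POSIXt") || inherits(t0, "POSIXt")) {
    as.numeric(difftime(t, t0, units = "mins"))
  } else {
    as.numeric(t) - as.numeric(t0)
  }
}

# Derive an independent substream seed from a master seed. Keeps the result
# strictly below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 1000003) %% 2147483629)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Tiny FNV-1a hash of a string, hex-encoded; used for run manifests.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
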