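# Internal helpers: deterministic seed derivation, local RNG scoping,
# report rounding.

# 32-bit multiply-accumulate without losing precision in doubles
mul32 <- function(a, b) {
  lo <- b %% 65536
  hi <- (b - lo) / 65536
  (a * lo + ((a * hi) %% 65536) * 65536) %% 4294967296
}

# FNV-1a over the UTF-8 bytes of a string; returns double in [0, 2^32)
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- mul32(bitwXor(as.integer(h %% 2147483648) , as.integer(b)) +
                 (h - h %% 2147483648), 16777619)
  }
  h
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Hashes the master seed together with an arbitrary set of labels
#' (subject, scan, assessor ids ...) so that every simulated entity owns an
#' independent, order-insensitive RNG stream. Adding subjects to a cohort
#' never reshuffles the draws of existing subjects.
#'
#' @param seed integer master seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), as.character, "")),
               collapse = "\x1f")
  as.integer(fnv1a32(key) %% 2147483647)
}

# Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' Report rounding used for printed percentage tables (R's `round()` uses
#' banker's rounding, which does not match clinical report conventions).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper)
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
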