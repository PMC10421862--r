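#' @keywords internal
"_PACKAGE"

## Small numeric helpers shared across modules. Conventions (documented in the
## methods vignette): SD uses the n-1 denominator; skewness and kurtosis are
## standardised sample moments (kurtosis reported as excess); a zero-variance
## sample has skewness 0 and kurtosis 0 by convention.

first_order_stats <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) {
    return(c(mean = NA_real_, median = NA_real_, sd = NA_real_,
             skewness = NA_real_, kurtosis = NA_real_))
  }
  m <- mean(x)
  s <- if (n > 1L) stats::sd(x) else 0
  if (!is.finite(s) || s == 0) {
    sk <- 0
    ku <- 0
  } else {
    m2 <- mean((x - m)^2)
    sk <- mean((x - m)^3) / m2^1.5
    ku <- mean((x - m)^4) / m2^2 - 3
  }
  c(mean = m, median = stats::median(x), sd = s, skewness = sk, kurtosis = ku)
}

## FNV-1a 32-bit hash over a character scalar; used for configuration and
## provenance hashes (stable across platforms, no external dependency).
fnv1a_hash <- function(x) {
  stopifnot(is.character(x))
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h >= 2^31)), b)
    h <- h %% 2^32
    ## 32-bit multiply by the FNV prime 16777619, done in two 16-bit halves
    ## to stay exact in doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- ((lo * 16777619) + (hi * 16777619 %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

## Canonical serialization of a (possibly nested) list of scalars/vectors for
## hashing: sorted names, fixed significant digits.
canonical_string <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    ord <- order(nm)
    parts <- vapply(ord, function(i) {
      paste0(nm[i], "=", canonical_string(x[[i]]))
    }, character(1))
    paste0("{", paste(parts, collapse = ";"), "}")
  } else if (is.numeric(x)) {
    paste(formatC(x, digits = 15, format = "g"), collapse = ",")
  } else {
    paste(as.character(x), collapse = ",")
  }
}

config_hash <- function(x) fnv1a_hash(canonical_string(x))

## Derive a stream-specific 31-bit seed from a base seed, so that every
## stochastic stage gets its own reproducible stream.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  (strtoi(substr(fnv1a_hash(key), 1, 7), 16L) %% .Machine$integer.max) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
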