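#' @keywords internal
"_PACKAGE"

# Stable 31-bit polynomial hash of a character string; used to fan a
# master seed out into per-stage / per-session seeds deterministically.
# Exact in double arithmetic: intermediate values stay below 2^53.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 1048573 + b) %% 2147483647
  h
}

#' Derive a reproducible child seed from a master seed and a tag
#'
#' @param master integer master seed.
#' @param tag character label of the consumer (stage, session id, ...).
#' @return An integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
derive_seed <- function(master, tag) {
  as.integer((fnv1a(paste0(master, "/", tag))) %% .Machine$integer.max)
}

# Row-wise softmax with max-subtraction for stability.
softmax_rows <- function(a) {
  a <- a - apply(a, 1L, max)
  e <- exp(a)
  e / rowSums(e)
}

relu <- function(x) x * (x > 0)

# clamp vector to closed interval
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Smooth a series with a centred moving average (edge-padded).
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
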