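#' Derive a substream seed from a master seed
#'
#' Deterministic counter scheme: stream k of master seed m is
#' `(m * 48271 + k * 104729) mod (2^31 - 1)`, kept strictly positive.
#' Adding a new stream index never perturbs existing streams, so adding a
#' scenario to a master run leaves the other scenarios' draws untouched.
#'
#' @param master integer master seed.
#' @param stream non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- (abs(as.double(master)) %% 2147483647) * 48271 + as.double(stream) * 104729
  as.integer(m %% 2147483646) + 1L
}

# Round half away from zero (base round() is round-half-to-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# FNV-1a 32-bit over a raw vector; returned as 8-char lowercase hex.
# Used for config hashes in run manifests (reproducible, not cryptographic).
fnv1a32 <- function(bytes) {
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h), b)
    # 32-bit multiply by 16777619 via 16-bit halves to stay exact in doubles
    lo <- bitwAnd(h, 65535L); hi <- bitwShiftR(h, 16)
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
    h <- as.integer(h - if (h > 2147483647) 4294967296 else 0)
  }
  sprintf("%08x", as.double(h) + if (h < 0) 4294967296 else 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
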