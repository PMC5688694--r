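# Internal helpers: error classes, seed derivation, tiny config hash.

stop_eegdloc <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "eegdloc_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

config_error <- function(msg) stop_eegdloc(msg, "eegdloc_config_error")
format_error <- function(msg) stop_eegdloc(msg, "eegdloc_format_error")
contract_error <- function(msg) stop_eegdloc(msg, "eegdloc_contract_error")
degenerate_channel_error <- function(msg) {
  stop_eegdloc(msg, "eegdloc_degenerate_channel")
}

#' Derive reproducible child seeds from a master seed
#'
#' Draws `n` independent integer seeds (each below 2^31) from a local RNG
#' stream seeded with `seed`, leaving the global RNG state untouched.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

# FNV-1a 32-bit hash of a character scalar; used to stamp output files with a
# config fingerprint without a hashing dependency.
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # h * 16777619 mod 2^32, split to stay within double precision
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
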