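# Internal helpers shared across modules.

abort_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("emgnetr_invalid_argument", "emgnetr_error")))
}

abort_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("emgnetr_parse_error", "emgnetr_error")))
}

abort_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("emgnetr_format_error", "emgnetr_error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

check_count <- function(x, name) {
  if (!is_count(x)) abort_invalid("`%s` must be a positive integer, got %s",
                                  name, deparse(substitute(x)))
  as.integer(x)
}

# FNV-1a 32-bit hash of a character string, as 8 hex digits.  Used for config
# fingerprints in manifests; not cryptographic.
fnv1a_hex <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # XOR touches only the low 8 bits since b < 256; keeps h a double safely
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by 16777619 using double arithmetic on 16-bit halves
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  hi16 <- floor(h / 65536)
  sprintf("%04x%04x", as.integer(hi16), as.integer(h - hi16 * 65536))
}

config_fingerprint <- function(x) {
  fnv1a_hex(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
}

# Derive a per-task seed from a master seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}
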