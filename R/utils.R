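# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so package functions never perturb the user's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# FNV-1a (32-bit) over a canonical JSON rendering of a configuration list.
# Only change-detection is required of this hash, not cryptographic strength.
# The multiply is split into 16-bit halves to stay inside exact double
# arithmetic.
config_hash <- function(x) {
  json <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                        force = TRUE, null = "null"))
  bytes <- utf8ToInt(json)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  h0 <- h %% 65536
  sprintf("%04x%04x", as.integer((h - h0) / 65536), as.integer(h0))
}

# Numeric formatter used by all table writers: full round-trip precision,
# scientific notation for small magnitudes.
format_numeric <- function(x) {
  out <- character(length(x))
  na <- is.na(x)
  out[na] <- "NA"
  small <- !na & x != 0 & abs(x) < 1e-4
  out[small] <- sprintf("%.16e", x[small])
  rest <- !na & !small
  out[rest] <- sprintf("%.17g", x[rest])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)

chrom_order_key <- function(chrom) {
  key <- suppressWarnings(as.numeric(gsub("^chr", "", as.character(chrom),
                                          ignore.case = TRUE)))
  key
}
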