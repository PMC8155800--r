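#' @importFrom stats dnorm pnorm qnorm qgamma qnbinom qpois rnorm runif
#'   quantile sd var setNames cor
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  if (!is.null(old <- get0(".Random.seed", globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Euro amounts are carried as integer cents internally; rounding to the
# cent happens once, when an amount enters the ledger.
as_cents <- function(euros) round(euros * 100)

cents_to_euros <- function(cents) cents / 100

# FNV-1a 32-bit hash of a character scalar, for config fingerprints.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

stop_prepost <- function(..., class = "prepostCE_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
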