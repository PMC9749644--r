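# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package functions never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive a reproducible sub-stream seed
#'
#' Deterministically mixes a base seed with one or more integer keys
#' (stage index, iteration number, ...) into a new seed below 2^31.
#' Every stage of the pipeline draws its seed from the single global seed
#' through this function, so one seed reproduces an entire run.
#'
#' @param seed base integer seed.
#' @param ... integer keys identifying the sub-stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  keys <- as.double(unlist(list(...)))
  s <- as.double(seed) %% 2147483647
  for (k in keys) {
    s <- (s * 48271 + k + 1) %% 2147483647
  }
  as.integer(s)
}

# stopifnot() with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

# FNV-1a 32-bit hash of a character scalar; used for config fingerprints in
# run manifests (stable across sessions, no external dependency).
# Arithmetic kept in doubles; the 32-bit product is split into 16-bit halves
# so intermediates stay within exact double range.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
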