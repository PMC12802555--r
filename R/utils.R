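# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a tag
#'
#' Deterministic, platform-independent mixing of a master seed with an
#' arbitrary set of tags (patient id, fraction, pipeline stage, ...), used so
#' that every stochastic unit of an experiment gets its own independent but
#' reproducible RNG stream. Result is always in `[1, 2^31 - 2]`.
#'
#' @param master Integer master seed.
#' @param ... Tags (coerced to character) identifying the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = ":")
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (c in utf8ToInt(key)) h <- (h * 131 + c) %% m
  as.integer(h %% (m - 2) + 1)
}

# Quintic smoothstep on [0, 1]; 0 below, 1 above.
smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * t * (t * (t * 6 - 15) + 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) if (!isTRUE(cond)) stopf(fmt, ...)
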