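# Internal helpers shared across modules.

BASES <- c("A", "G", "C", "T")  # bit order within a one-hot block

#' Evaluate an expression with a local, restorable RNG state
#'
#' Seeds R's RNG with `seed`, runs `code`, and restores the previous
#' `.Random.seed`, so seeded package internals never disturb the caller's
#' random stream.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  code
}

#' Derive a child seed deterministically from a master seed
#'
#' Lehmer-style mixing kept below 2^31 so any grid cell, restart or library
#' draw is reproducible in isolation from the master seed plus its indices.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the child stream.
#' @return integer seed in \[1, 2^31 - 2\].
#' @export
#' @examples
#' derive_seed(1L, 3, 7)
derive_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- as.numeric(master) %% m
  for (ix in c(...)) {
    s <- (s * 16807 + as.numeric(ix) + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# stop() with a call-free, sprintf-formatted message
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
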