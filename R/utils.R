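# Seed plumbing for reproducible, independent random streams.

#' Derive a child seed from a master seed and integer indices
#'
#' Hashes a master seed together with any number of integer indices
#' (participant, condition, trial, replicate, ...) into a deterministic
#' 31-bit seed, so that every generated unit has its own reproducible
#' random stream. Uses a Lehmer-style multiplicative mix modulo 2^31-1.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the unit.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @examples
#' deriveSeed(42, 3, 1, 2)
#' @export
deriveSeed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647
  h <- (abs(as.double(master)) + 1) %% m
  for (k in idx) {
    h <- (h * 48271) %% m
    h <- (h + abs(as.double(k)) + 1) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Internal: stop with a consistent parameter-error message.
checkPositiveScalar <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(x)
}
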