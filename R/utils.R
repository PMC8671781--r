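# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

rms <- function(x) sqrt(mean(x^2))

vlog <- function(stage, ...) {
  if (isTRUE(getOption("beelfp.verbose", FALSE))) {
    message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
  }
  invisible(NULL)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# Count zero crossings, ignoring exact zeros (sign changes of the nonzero part).
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0L)
}

# Strip S3 classes from nested lists (for JSON serialization).
unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

# Reflect a vector into [lo, hi] (triangle-wave folding).
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}
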