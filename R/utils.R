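# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL means "use the ambient stream", so experiment drivers can seed
# once and have every nested stochastic step draw from the same stream.
with_seed_or_stream <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_percnorm <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_percnorm(...)
  invisible(TRUE)
}

# collapse a character vector for error messages, capped
oxford <- function(x, max = 5L) {
  x <- as.character(x)
  if (length(x) > max) {
    paste0(paste(x[seq_len(max)], collapse = ", "), ", ... (", length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}
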