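# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "erpcsp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x > 0 && x == round(x)

# Run `fun` (a zero-argument function) under a fixed RNG seed, restoring the
# caller's RNG state afterwards so package internals never perturb user code.
with_seed <- function(seed, fun) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  fun()
}

# Derive a child seed from a master seed and a stream label; keeps results
# reproducible while decoupling the generator, fold and permutation streams.
# Stays below 2^31 - 1.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# Linear convolution of each row of `x` (channels x samples) with kernel `h`,
# returning the "same"-size central part, via FFT. Equivalent to
# stats::convolve(type = "open") row-wise but much faster for long kernels.
conv_same_rows <- function(x, h) {
  n <- ncol(x)
  nh <- length(h)
  nfull <- n + nh - 1L
  nfft <- 2^ceiling(log2(nfull))
  H <- stats::fft(c(h, rep(0, nfft - nh)))
  xp <- cbind(x, matrix(0, nrow(x), nfft - n))
  X <- stats::mvfft(t(xp))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  half <- (nh - 1L) %/% 2L
  t(y)[, (half + 1L):(half + n), drop = FALSE]
}
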