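# Internal helpers shared across modules.

# Deterministic seed derivation: every stochastic component draws its own
# stream from (seed, counter...) so results do not depend on generation order.
# Arithmetic stays below 2^53, result below 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (k in idx) {
    h <- (h * 69069 + as.double(k) * 1234567 + 12345) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Central-difference derivative of a vector sampled at times t (seconds).
central_diff <- function(x, t) {
  n <- length(x)
  if (n < 2L) {
    return(rep(NA_real_, n))
  }
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L) {
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  d
}

# Moving-average smoother with centred window of `width` samples (odd-ified).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) < width) {
    return(x)
  }
  kernel <- rep(1 / width, width)
  pad <- (width - 1L) %/% 2L
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  as.numeric(stats::filter(xp, kernel, sides = 2))[(pad + 1L):(pad + length(x))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
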