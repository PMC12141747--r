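# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so every generator is a pure
#' function of its seed argument.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and one or more integer indices,
# staying inside the 32-bit signed range.
child_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in idx) {
    x <- (x * 69069 + as.double(k) * 40014 + 12345) %% 2147483563
  }
  as.integer(x %% 2147483399) + 1L
}

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal of a real vector (Hilbert construction:
#' negative frequencies zeroed, positive doubled).
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 4L)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Raised-cosine band-pass gain evaluated on an FFT frequency grid.
# Passband [lo, hi], transition width tw on each side.
rc_band_gain <- function(f, lo, hi, tw) {
  g <- numeric(length(f))
  core <- f >= lo & f <= hi
  g[core] <- 1
  lo_ramp <- f > (lo - tw) & f < lo
  g[lo_ramp] <- 0.5 * (1 + cos(pi * (lo - f[lo_ramp]) / tw))
  hi_ramp <- f > hi & f < (hi + tw)
  g[hi_ramp] <- 0.5 * (1 + cos(pi * (f[hi_ramp] - hi) / tw))
  g
}

#' Zero-phase band-pass + analytic signal in one inverse FFT
#'
#' Multiplies the spectrum by a raised-cosine band-pass gain restricted to
#' positive frequencies (doubled), which is simultaneously an exactly
#' zero-phase band-pass filter and the Hilbert analytic-signal construction.
#' @noRd
band_analytic <- function(x, fs, lo, hi, transition = NULL, X_fft = NULL) {
  n <- if (is.null(X_fft)) length(x) else length(X_fft)
  stopifnot(n >= 8L, fs > 0, lo > 0, hi > lo)
  if (hi > fs / 2) {
    stop("amplitude/phase band upper edge ", hi,
         " Hz exceeds Nyquist frequency ", fs / 2, " Hz")
  }
  tw <- transition %||% min(2, max(0.5, 0.15 * (hi - lo)))
  tw <- min(tw, lo * 0.9)  # keep the lower ramp above DC
  f <- (seq_len(n) - 1L) * fs / n
  pos <- f <= fs / 2
  g <- numeric(n)
  g[pos] <- rc_band_gain(f[pos], lo, hi, tw)
  # analytic weighting: zero negative freqs, double strictly-positive ones
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  X <- X_fft %||% stats::fft(x)
  stats::fft(X * g * h, inverse = TRUE) / n
}

# Merge a list of half-open sample intervals (1-based starts, exclusive ends)
# into a disjoint sorted set.
merge_intervals <- function(iv) {
  if (length(iv) == 0L) return(list())
  m <- do.call(rbind, lapply(iv, function(p) c(p[[1]], p[[2]])))
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  if (nrow(m) == 0L) return(list())
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- list(m[1, ])
  for (i in seq_len(nrow(m))[-1]) {
    last <- out[[length(out)]]
    if (m[i, 1] <= last[2]) {
      out[[length(out)]] <- c(last[1], max(last[2], m[i, 2]))
    } else {
      out[[length(out) + 1L]] <- m[i, ]
    }
  }
  lapply(out, function(p) c(start = p[1], end = p[2]))
}

# Logical mask of retained samples given merged bad segments.
retained_mask <- function(n, bad_segments) {
  keep <- rep(TRUE, n)
  for (seg in bad_segments) {
    a <- max(1L, as.integer(seg[[1]]))
    b <- min(n, as.integer(seg[[2]]) - 1L)
    if (b >= a) keep[a:b] <- FALSE
  }
  keep
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= 0
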