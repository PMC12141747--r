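#' Canonical EEG frequency bands
#'
#' The four analysis bands: theta (4-8 Hz), alpha (8-13 Hz), beta (13-30 Hz)
#' and gamma (30-60 Hz). Band-edge membership is half-open `[lo, hi)`
#' throughout the package, so 8 Hz belongs to alpha and 13 Hz to beta.
#'
#' @param theta,alpha,beta,gamma Numeric length-2 `(lo, hi)` edges in Hz.
#' @return An object of class `band_set`: a named list of `(lo, hi)` pairs.
#' @examples
#' band_set()
#' @export
band_set <- function(theta = c(4, 8), alpha = c(8, 13),
                     beta = c(13, 30), gamma = c(30, 60)) {
  bs <- list(theta = theta, alpha = alpha, beta = beta, gamma = gamma)
  for (nm in names(bs)) {
    b <- bs[[nm]]
    if (length(b) != 2L || !is.numeric(b) || b[1] >= b[2] || b[1] <= 0) {
      stop("band '", nm, "' must be a (lo, hi) pair with 0 < lo < hi")
    }
  }
  ord <- c("theta", "alpha", "beta", "gamma")
  for (i in 1:3) {
    if (bs[[ord[i]]][2] > bs[[ord[i + 1]]][1]) {
      stop("bands must be non-overlapping (shared edges allowed): ",
           ord[i], " overlaps ", ord[i + 1])
    }
  }
  structure(bs, class = "band_set")
}

#' @export
print.band_set <- function(x, ...) {
  cat("EEG band set (half-open [lo, hi) membership):\n")
  for (nm in names(x)) {
    cat(sprintf("  %-6s %g-%g Hz\n", nm, x[[nm]][1], x[[nm]][2]))
  }
  invisible(x)
}

# Membership of frequencies in a half-open band.
in_band <- function(f, band) f >= band[1] & f < band[2]

#' Phase-amplitude frequency pairs under analysis
#'
#' @return Character vector of the three analysed pairs.
#' @export
pac_pairs <- function() c("theta-gamma", "alpha-gamma", "beta-gamma")

phase_band_of_pair <- function(pair) {
  sub("-gamma$", "", pair)
}
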