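# Clean-segment bookkeeping: start/end (inclusive) sample runs of retained data.
clean_runs <- function(n, bad_segments) {
  keep <- retained_mask(n, bad_segments)
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Welch power spectral density per channel
#'
#' Hann-windowed Welch periodogram averaged over all complete windows within
#' clean segments (bad segments never contribute). One-sided density in
#' signal-units^2/Hz; frequency resolution `1 / window_s`. Band powers are
#' the mean of `10 * log10(psd)` over in-band bins (dB/Hz convention), with
#' half-open `[lo, hi)` band membership.
#'
#' @param rec A preprocessed `eeg_recording`.
#' @param window_s Window length in seconds (default 2).
#' @param overlap Fractional overlap between windows (default 0.5).
#' @param bands A [band_set()].
#' @return A list of per-channel results, each with `channel`, `freqs`,
#'   `psd` and `band_power` (named numeric, dB/Hz; `-Inf` marks a band with
#'   zero power, treated as missing downstream).
#' @export
compute_psd <- function(rec, window_s = 2, overlap = 0.5,
                        bands = band_set()) {
  stopifnot(inherits(rec, "eeg_recording"))
  stopifnot(window_s > 0, overlap >= 0, overlap < 1)
  fs <- rec$fs
  nwin <- round(window_s * fs)
  step <- max(1L, round(nwin * (1 - overlap)))
  runs <- clean_runs(ncol(rec$data), rec$bad_segments)
  if (nrow(runs) == 0L || max(runs[, "end"] - runs[, "start"] + 1L) < nwin) {
    stop("window_s = ", window_s, " s is longer than every clean segment")
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / nwin)  # Hann
  norm <- fs * sum(w^2)
  half <- nwin %/% 2L
  freqs <- (0:half) * fs / nwin
  lapply(seq_len(nrow(rec$data)), function(ci) {
    acc <- numeric(half + 1L)
    count <- 0L
    for (ri in seq_len(nrow(runs))) {
      a <- runs[ri, "start"]; b <- runs[ri, "end"]
      if (b - a + 1L < nwin) next
      starts <- seq(a, b - nwin + 1L, by = step)
      for (s in starts) {
        seg <- rec$data[ci, s:(s + nwin - 1L)]
        X <- stats::fft((seg - mean(seg)) * w)
        p <- Mod(X[1:(half + 1L)])^2 / norm
        p[2:half] <- 2 * p[2:half]  # one-sided (DC and Nyquist not doubled)
        acc <- acc + p
        count <- count + 1L
      }
    }
    psd <- acc / count
    bp <- vapply(bands, function(b) {
      sel <- in_band(freqs, b)
      if (!any(sel)) return(NA_real_)
      mean(10 * log10(psd[sel]))
    }, 0)
    list(channel = rec$channel_labels[ci], freqs = freqs, psd = psd,
         band_power = bp)
  })
}

#' Long band-power table for a cohort
#'
#' One row per subject x recoded electrode (Cd, Cn, Cz, Fz, Pz) x band,
#' with C3/C4 mapped through each subject's handedness. Feeds the
#' mixed-model group analysis.
#'
#' @param recordings List of preprocessed `eeg_recording` objects.
#' @param window_s,overlap,bands Passed to [compute_psd()].
#' @return data.frame with columns `subject_id`, `group`, `electrode`,
#'   `band`, `power` (dB/Hz). Electrodes missing from a recording yield no
#'   row (with a warning); non-finite band powers become `NA`.
#' @export
band_power_table <- function(recordings, window_s = 2, overlap = 0.5,
                             bands = band_set()) {
  rows <- list()
  for (rec in recordings) {
    psds <- compute_psd(rec, window_s, overlap, bands)
    have <- vapply(psds, function(p) p$channel, "")
    expected <- c("C3", "C4", "Cz", "Fz", "Pz")
    missing <- setdiff(expected, have)
    if (length(missing)) {
      warning("subject ", rec$subject_id, ": electrode(s) ",
              paste(missing, collapse = ", "), " absent; rows omitted")
    }
    for (p in psds) {
      if (!p$channel %in% expected) next
      el <- recoded_label(p$channel, rec$handedness)
      for (b in names(p$band_power)) {
        v <- p$band_power[[b]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = rec$subject_id, group = rec$group, electrode = el,
          band = b, power = if (is.finite(v)) v else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
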