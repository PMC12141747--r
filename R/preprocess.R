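#' Preprocessing configuration
#'
#' The EEG conditioning chain: resample to 400 Hz, average reference,
#' 50-Hz notch, 2-60 Hz band-pass, then artifact screening by a
#' cross-channel RMS z-score rule on 1-s windows.
#'
#' @param target_fs Output sampling rate, Hz (default 400).
#' @param notch_hz Mains frequency to notch out (default 50).
#' @param bandpass `(lo, hi)` band-pass edges in Hz (default `c(2, 60)`).
#' @param reference `"average"` or `"none"`.
#' @param reject_zscore Robust z-score threshold on windowed cross-channel
#'   RMS above which a window is marked bad (default 5).
#' @param min_clean_s Minimum total retained duration in seconds; shorter
#'   recordings raise an "unusable recording" error (default 60).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 400, notch_hz = 50,
                              bandpass = c(2, 60), reference = "average",
                              reject_zscore = 5, min_clean_s = 60) {
  reference <- match.arg(reference, c("average", "none"))
  stopifnot(length(bandpass) == 2L, bandpass[1] < bandpass[2])
  if (target_fs < 2 * bandpass[2]) {
    stop("target_fs must be at least twice the band-pass upper edge")
  }
  structure(list(target_fs = target_fs, notch_hz = notch_hz,
                 bandpass = bandpass, reference = reference,
                 reject_zscore = reject_zscore, min_clean_s = min_clean_s),
            class = "preprocess_config")
}

# Forward-backward filtering of each row of a channels x samples matrix.
filtfilt_rows <- function(filt, data) {
  out <- data
  for (i in seq_len(nrow(data))) {
    out[i, ] <- signal::filtfilt(filt, data[i, ])
  }
  out
}

#' Preprocess an EEG recording
#'
#' Applies, in order: resampling to `target_fs` (polyphase), average
#' re-referencing, zero-phase forward-backward IIR notch (2nd-order, Q = 30)
#' and band-pass (cascaded 4th-order Butterworth high- and low-pass), then
#' marks bad segments: the first and last second (filter transients) and any
#' 1-s window whose cross-channel RMS exceeds `reject_zscore` robust z-scores
#' of the window distribution. Errors if less than `min_clean_s` of clean
#' signal remains.
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [preprocess_config()].
#' @return The cleaned `eeg_recording` (fs = `target_fs`, bad segments in
#'   post-resampling sample coordinates).
#' @export
preprocess <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  stopifnot(inherits(cfg, "preprocess_config"))
  if (rec$fs < cfg$target_fs) {
    stop("recording fs (", rec$fs, ") below target_fs (", cfg$target_fs, ")")
  }
  data <- rec$data
  if (cfg$reference == "average" && nrow(data) < 2L) {
    stop("average reference requires at least 2 channels")
  }
  fs <- rec$fs
  if (fs != cfg$target_fs) {
    ratio <- fs / cfg$target_fs
    new_n <- floor(ncol(data) * cfg$target_fs / fs)
    res <- matrix(0, nrow(data), new_n, dimnames = list(rownames(data), NULL))
    for (i in seq_len(nrow(data))) {
      y <- signal::resample(data[i, ], p = cfg$target_fs, q = fs)
      res[i, ] <- y[seq_len(new_n)]
    }
    data <- res
    fs <- cfg$target_fs
    if (length(rec$bad_segments)) {
      rec$bad_segments <- lapply(rec$bad_segments, function(seg) {
        c(floor((seg[[1]] - 1) / ratio) + 1, ceiling(seg[[2]] / ratio))
      })
    }
  }
  if (cfg$reference == "average") {
    data <- sweep(data, 2L, colMeans(data))
  }
  # 2nd-order notch, Q = 30
  bw <- cfg$notch_hz / 30
  ntch <- signal::butter(2, c(cfg$notch_hz - bw / 2, cfg$notch_hz + bw / 2) /
                           (fs / 2), type = "stop")
  data <- filtfilt_rows(ntch, data)
  # cascaded high-pass + low-pass (stable at the low normalized edge)
  hp <- signal::butter(4, cfg$bandpass[1] / (fs / 2), type = "high")
  lp <- signal::butter(4, cfg$bandpass[2] / (fs / 2), type = "low")
  data <- filtfilt_rows(lp, filtfilt_rows(hp, data))

  n <- ncol(data)
  bad <- rec$bad_segments
  # filter transients: first and last second
  bad <- c(bad, list(c(1, fs + 1), c(n - fs + 1, n + 1)))
  # windowed cross-channel RMS screening
  win <- as.integer(fs)
  n_win <- floor(n / win)
  if (n_win >= 4L) {
    rms <- vapply(seq_len(n_win), function(w) {
      idx <- ((w - 1L) * win + 1L):(w * win)
      sqrt(mean(data[, idx]^2))
    }, 0)
    med <- stats::median(rms)
    scale <- stats::mad(rms)
    if (scale > 0) {
      z <- (rms - med) / scale
      for (w in which(z > cfg$reject_zscore)) {
        bad <- c(bad, list(c((w - 1L) * win + 1L, w * win + 1L)))
      }
    }
  }
  bad <- merge_intervals(bad)
  retained <- sum(retained_mask(n, bad)) / fs
  if (retained < cfg$min_clean_s) {
    stop("unusable recording: only ", round(retained, 1),
         " s clean data retained (< ", cfg$min_clean_s, " s required)")
  }
  rec$data <- data
  rec$fs <- fs
  rec$bad_segments <- bad
  rec
}

#' Recode central electrodes by handedness
#'
#' Maps C3/C4 to the handedness-related dominant (Cd) and non-dominant (Cn)
#' hemisphere labels: Cd = C3 and Cn = C4 in right-handers, and vice versa
#' in left-handers. Cz, Fz and Pz pass through unchanged.
#'
#' @param labels Channel labels; must contain `"C3"` and `"C4"`.
#' @param handedness `"right"` or `"left"` (no default: unknown handedness
#'   is an error).
#' @return A list with `Cd`, `Cn` (source labels) and `passthrough`.
#' @examples
#' recode_by_handedness(c("C3", "C4", "Cz"), "right")$Cd  # "C3"
#' @export
recode_by_handedness <- function(labels, handedness) {
  if (missing(handedness) || length(handedness) != 1L ||
      !handedness %in% c("right", "left")) {
    stop("handedness must be 'right' or 'left'")
  }
  if (!all(c("C3", "C4") %in% labels)) {
    stop("labels must contain both C3 and C4")
  }
  list(Cd = if (handedness == "right") "C3" else "C4",
       Cn = if (handedness == "right") "C4" else "C3",
       passthrough = intersect(c("Cz", "Fz", "Pz"), labels))
}

# Recoded label of a physical electrode for one subject.
recoded_label <- function(electrode, handedness) {
  rc <- recode_by_handedness(c("C3", "C4", electrode), handedness)
  if (electrode == rc$Cd) "Cd"
  else if (electrode == rc$Cn) "Cn"
  else electrode
}
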