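#' Kullback-Leibler modulation index
#'
#' The Tort-style phase-amplitude coupling statistic. Phases are binned into
#' `n_phase_bins` equal-width, left-closed bins partitioning `[-pi, pi)`;
#' `P_j` is the mean amplitude in bin j normalized to sum to one; the index
#' is the KL divergence of `P` from the uniform distribution normalized by
#' its maximum: `MI = (log N - H(P)) / log N` with `H` the Shannon entropy
#' in nats (the index is log-base invariant). `MI = 0` means amplitude is
#' independent of phase; `MI = 1` means all amplitude mass in one bin.
#'
#' An empty phase bin raises an "insufficient phase coverage" error: with at
#' least `10 * n_phase_bins` samples of continuous phase, an empty bin
#' indicates a broken decomposition, and smoothing it over would bias MI.
#'
#' @param phase Numeric vector of phases in radians (any branch; wrapped
#'   internally to `[-pi, pi)`).
#' @param amp Non-negative amplitude envelope, same length as `phase`.
#' @param n_phase_bins Number of phase bins N (default 18, i.e. 20-degree
#'   bins).
#' @return An object of class `phase_bin_distribution` with fields
#'   `n_phase_bins`, `edges`, `counts`, `mean_amp`, `P`, `H`, `MI`.
#' @examples
#' ph <- seq(-pi, pi - 1e-6, length.out = 3600)
#' mi <- modulation_index(ph, 1 + cos(ph), 18)
#' mi$MI
#' @export
modulation_index <- function(phase, amp, n_phase_bins = 18L) {
  n <- length(phase)
  N <- as.integer(n_phase_bins)
  stopifnot(N >= 2L)
  if (length(amp) != n) stop("phase and amp must have equal length")
  if (n < 10L * N) {
    stop("series too short: need at least 10 * n_phase_bins = ", 10L * N,
         " samples, got ", n)
  }
  if (any(!is.finite(phase)) || any(!is.finite(amp))) {
    stop("phase/amp contain non-finite values")
  }
  if (any(amp < 0)) stop("amplitude envelope must be non-negative")
  if (all(amp == 0)) stop("amplitude series is all zero")
  ph <- ((phase + pi) %% (2 * pi)) - pi
  bin <- floor((ph + pi) / (2 * pi) * N) + 1L
  bin[bin > N] <- N
  counts <- tabulate(bin, N)
  if (any(counts == 0L)) {
    stop("insufficient phase coverage: empty phase bin")
  }
  sums <- as.numeric(rowsum(amp, bin))
  mean_amp <- sums / counts
  P <- mean_amp / sum(mean_amp)
  H <- -sum(P[P > 0] * log(P[P > 0]))
  structure(list(
    n_phase_bins = N,
    edges = seq(-pi, pi, length.out = N + 1L),
    counts = counts, mean_amp = mean_amp, P = P, H = H,
    MI = (log(N) - H) / log(N)
  ), class = "phase_bin_distribution")
}

#' @export
print.phase_bin_distribution <- function(x, ...) {
  cat(sprintf("<phase_bin_distribution> N = %d bins, H = %.4f nats, MI = %.6g\n",
              x$n_phase_bins, x$H, x$MI))
  invisible(x)
}

#' Extract instantaneous phase and amplitude envelope
#'
#' Band-passes the signal in the phase band and the amplitude band
#' (zero-phase frequency-domain filters with raised-cosine transitions) and
#' takes the analytic-signal angle and magnitude respectively. Samples in
#' bad segments and within `edge_trim_s` of the recording edges (filter
#' transients) are excluded.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate, Hz.
#' @param phase_band,amp_band `(lo, hi)` edges in Hz.
#' @param bad_segments List of half-open sample intervals to exclude.
#' @param edge_trim_s Seconds trimmed from each end (default 1).
#' @param valid_range Analysis band-pass; bands outside it are an error
#'   (default `c(2, 60)`, the preprocessing band).
#' @return List with `phase` (radians), `amp` (envelope, >= 0) and `idx`
#'   (retained sample indices).
#' @export
extract_phase_amp <- function(x, fs, phase_band, amp_band,
                              bad_segments = list(), edge_trim_s = 1,
                              valid_range = c(2, 60)) {
  stopifnot(length(phase_band) == 2L, length(amp_band) == 2L)
  if (fs <= 2 * amp_band[2]) {
    stop("fs = ", fs, " Hz too low for amplitude band upper edge ",
         amp_band[2], " Hz")
  }
  if (!is.null(valid_range)) {
    if (phase_band[1] < valid_range[1] || amp_band[2] > valid_range[2]) {
      stop("requested bands fall outside the preprocessing band-pass (",
           valid_range[1], "-", valid_range[2], " Hz)")
    }
  }
  n <- length(x)
  ph <- Arg(band_analytic(x, fs, phase_band[1], phase_band[2]))
  am <- Mod(band_analytic(x, fs, amp_band[1], amp_band[2]))
  keep <- retained_mask(n, bad_segments)
  trim <- round(edge_trim_s * fs)
  if (trim > 0 && n > 2 * trim) {
    keep[seq_len(trim)] <- FALSE
    keep[(n - trim + 1L):n] <- FALSE
  }
  idx <- which(keep)
  list(phase = ph[idx], amp = am[idx], idx = idx)
}

#' Phase-amplitude frequency grid for comodulograms
#'
#' Phase axis spans 2-30 Hz, amplitude axis 30-60 Hz. The default
#' "desk-scale" grid uses 2-Hz phase steps and 5-Hz amplitude steps;
#' `fine = TRUE` switches to 100 evenly spaced centers per axis. Filter
#' bandwidths are `phase_bw` (default 2 Hz) and `amp_bw` (default 10 Hz).
#'
#' @param phase_axis,amp_axis Explicit center frequencies (Hz); override
#'   the defaults when given.
#' @param phase_bw,amp_bw Filter bandwidths in Hz.
#' @param fine Use 100 centers per axis instead of the coarse grid.
#' @return Object of class `pac_grid`.
#' @export
pac_grid <- function(phase_axis = NULL, amp_axis = NULL,
                     phase_bw = 2, amp_bw = 10, fine = FALSE) {
  if (is.null(phase_axis)) {
    phase_axis <- if (fine) seq(2 + phase_bw / 2, 30 - phase_bw / 2,
                                length.out = 100)
                  else seq(3, 29, by = 2)
  }
  if (is.null(amp_axis)) {
    amp_axis <- if (fine) seq(30, 60, length.out = 100)
                else seq(32.5, 57.5, by = 5)
  }
  stopifnot(all(diff(phase_axis) > 0), all(diff(amp_axis) > 0))
  stopifnot(phase_bw > 0, amp_bw > 0)
  if (phase_bw >= 2 * min(phase_axis)) {
    stop("phase_bw must be below the minimum phase frequency ",
         "(phase must be resolvable)")
  }
  structure(list(phase_axis = phase_axis, amp_axis = amp_axis,
                 phase_bw = phase_bw, amp_bw = amp_bw),
            class = "pac_grid")
}

#' One-cell-per-pair grid over the canonical bands
#'
#' A minimal [pac_grid()] with one phase cell per slow band (theta, alpha,
#' beta; filter bandwidth = band width) and one gamma amplitude cell. The
#' mean MI over a band region on this grid is the direct band-level
#' modulation index; used by the Monte-Carlo study helpers for speed.
#'
#' @param bands A [band_set()].
#' @return Object of class `pac_grid`.
#' @export
band_grid <- function(bands = band_set()) {
  centers <- vapply(bands[c("theta", "alpha", "beta")], mean, 0)
  widths <- vapply(bands[c("theta", "alpha", "beta")], diff, 0)
  g <- pac_grid(phase_axis = unname(centers),
                amp_axis = mean(bands$gamma),
                phase_bw = min(widths), amp_bw = diff(bands$gamma))
  g$cell_bw <- unname(widths)  # per-cell phase bandwidths (full band width)
  g
}

#' Compute a comodulogram
#'
#' Modulation index over every (phase frequency, amplitude frequency) cell
#' of a [pac_grid()]: `mi[i, j]` uses the phase filter centered at
#' `phase_axis[i]` (width `phase_bw`) and the amplitude filter centered at
#' `amp_axis[j]` (width `amp_bw`). A cell whose MI computation fails is set
#' to `NaN` with a warning; more than 10% failed cells aborts.
#'
#' @param x Numeric signal vector (preprocessed, clean-segment aware via
#'   `bad_segments`).
#' @param fs Sampling rate, Hz.
#' @param grid A [pac_grid()].
#' @param n_phase_bins Phase bins for [modulation_index()] (default 18).
#' @param bad_segments Half-open sample intervals to exclude.
#' @param valid_range Passed to [extract_phase_amp()]; set `NULL` to skip
#'   the band-range check.
#' @return Object of class `comodulogram`: `grid`, `mi` matrix
#'   (`|phase_axis| x |amp_axis|`), `n_phase_bins`.
#' @export
comodulogram <- function(x, fs, grid = pac_grid(), n_phase_bins = 18L,
                         bad_segments = list(), valid_range = NULL) {
  stopifnot(inherits(grid, "pac_grid"))
  n <- length(x)
  keep <- retained_mask(n, bad_segments)
  trim <- round(fs)
  if (n > 2 * trim) {
    keep[seq_len(trim)] <- FALSE
    keep[(n - trim + 1L):n] <- FALSE
  }
  idx <- which(keep)
  X <- stats::fft(x)
  phase_bw <- grid$cell_bw %||% rep(grid$phase_bw, length(grid$phase_axis))
  phases <- lapply(seq_along(grid$phase_axis), function(i) {
    f0 <- grid$phase_axis[i]
    Arg(band_analytic(x, fs, f0 - phase_bw[i] / 2, f0 + phase_bw[i] / 2,
                      X_fft = X))[idx]
  })
  amps <- lapply(grid$amp_axis, function(f0) {
    Mod(band_analytic(x, fs, f0 - grid$amp_bw / 2, f0 + grid$amp_bw / 2,
                      X_fft = X))[idx]
  })
  mi <- matrix(NA_real_, length(grid$phase_axis), length(grid$amp_axis),
               dimnames = list(sprintf("%g", grid$phase_axis),
                               sprintf("%g", grid$amp_axis)))
  n_fail <- 0L
  for (i in seq_along(phases)) {
    for (j in seq_along(amps)) {
      mi[i, j] <- tryCatch(
        modulation_index(phases[[i]], amps[[j]], n_phase_bins)$MI,
        error = function(e) {
          n_fail <<- n_fail + 1L
          NaN
        })
    }
  }
  if (n_fail > 0L) {
    if (n_fail > 0.1 * length(mi)) {
      stop("comodulogram failed: ", n_fail, " of ", length(mi),
           " cells could not be computed")
    }
    warning(n_fail, " comodulogram cell(s) failed; set to NaN")
  }
  structure(list(grid = grid, mi = mi, n_phase_bins = n_phase_bins),
            class = "comodulogram")
}

#' Mean modulation index over a frequency-pair region
#'
#' Arithmetic mean of comodulogram cells whose phase center lies in the
#' pair's slow band and amplitude center in the gamma band (half-open band
#' edges), the per-subject summary used for group-level analyses.
#'
#' @param com A [comodulogram()].
#' @param pair One of `"theta-gamma"`, `"alpha-gamma"`, `"beta-gamma"`.
#' @param bands A [band_set()].
#' @return Single numeric mean MI.
#' @export
mean_mi <- function(com, pair, bands = band_set()) {
  stopifnot(inherits(com, "comodulogram"))
  pair <- match.arg(pair, pac_pairs())
  pb <- bands[[phase_band_of_pair(pair)]]
  gb <- bands$gamma
  pi_sel <- in_band(com$grid$phase_axis, pb)
  pj_sel <- in_band(com$grid$amp_axis, gb)
  if (!any(pi_sel) || !any(pj_sel)) {
    stop("comodulogram grid has no cells inside the ", pair, " region")
  }
  mean(com$mi[pi_sel, pj_sel])
}

#' Per-subject PAC summary table for a cohort
#'
#' Computes a comodulogram per subject and electrode of interest and
#' extracts the mean MI per frequency pair, with C3/C4 recoded to Cd/Cn by
#' handedness.
#'
#' @param recordings List of preprocessed `eeg_recording` objects.
#' @param grid A [pac_grid()] (default coarse grid; use
#'   `pac_grid(fine = TRUE)` for the 100-per-axis resolution or
#'   [band_grid()] for the fast band-level summary).
#' @param n_phase_bins Phase bins (default 18).
#' @param bands A [band_set()].
#' @return data.frame with columns `subject_id`, `group`, `electrode`
#'   (Cd, Cn, Cz, Fz, Pz), `pair`, `mean_mi`.
#' @export
pac_table <- function(recordings, grid = pac_grid(), n_phase_bins = 18L,
                      bands = band_set()) {
  rows <- list()
  expected <- c("C3", "C4", "Cz", "Fz", "Pz")
  for (rec in recordings) {
    for (el in intersect(expected, rec$channel_labels)) {
      x <- rec$data[match(el, rec$channel_labels), ]
      com <- comodulogram(x, rec$fs, grid, n_phase_bins,
                          bad_segments = rec$bad_segments)
      for (pair in pac_pairs()) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = rec$subject_id, group = rec$group,
          electrode = recoded_label(el, rec$handedness), pair = pair,
          mean_mi = mean_mi(com, pair, bands), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
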