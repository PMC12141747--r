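#' Configuration for a synthetic EEG cohort
#'
#' Describes the study conditions emulated by the generator: 5-minute
#' eyes-closed resting-state recordings at 400 Hz on the five analysis
#' electrodes, a 1/f aperiodic background with superimposed narrowband
#' oscillations, and injectable phase-amplitude coupling that may differ by
#' group and electrode.
#'
#' @param n_per_group Subjects per group (controls and ALS); at least 2.
#' @param fs Sampling rate in Hz (default 400).
#' @param duration_s Recording duration in seconds (default 300).
#' @param electrodes Channel labels generated (default the five analysis
#'   electrodes C3, C4, Cz, Fz, Pz).
#' @param seed Integer master seed; every generated quantity is a pure
#'   function of it.
#' @param aperiodic_exponent Spectral exponent beta of the 1/f^beta
#'   background (default 1).
#' @param background_rms Root-mean-square amplitude of the aperiodic
#'   background in microvolts (default 5).
#' @param band_amplitudes Named numeric vector of oscillation amplitudes in
#'   microvolts per band (theta, alpha, beta, gamma).
#' @param coupling List of [coupling_spec()] entries; electrodes may be given
#'   as recoded labels (`"Cd"`, `"Cn"`), resolved per subject by handedness.
#' @param depth_sd Between-subject SD of realized coupling depth: each
#'   subject's depth is drawn from a normal centred on the spec depth,
#'   truncated to `[0, 1]` (jitter applies only to specs with depth > 0, so
#'   an uncoupled condition stays exactly uncoupled). Calibrated so the
#'   group contrast at the coupled electrode lands near the reported
#'   between-group effect size; set 0 for deterministic depths.
#' @param handedness_fraction_right Fraction of right-handed subjects per
#'   group (default 23/26, the patient-cohort proportion).
#' @param n_extra_channels Number of additional background-only dummy
#'   channels (useful for exercising average referencing); default 0.
#' @return An object of class `cohort_config`.
#' @seealso [generate_subject_eeg()], [generate_cohort()]
#' @export
cohort_config <- function(n_per_group = 26,
                          fs = 400,
                          duration_s = 300,
                          electrodes = c("C3", "C4", "Cz", "Fz", "Pz"),
                          seed = 1L,
                          aperiodic_exponent = 1.0,
                          background_rms = 5,
                          band_amplitudes = c(theta = 5, alpha = 8,
                                              beta = 3, gamma = 2),
                          coupling = default_coupling(),
                          depth_sd = 0.3,
                          handedness_fraction_right = 23 / 26,
                          n_extra_channels = 0L) {
  stopifnot(is_count(n_per_group), n_per_group >= 2)
  stopifnot(fs > 0, duration_s > 0)
  stopifnot(all(band_amplitudes >= 0))
  bad <- setdiff(names(band_amplitudes), c("theta", "alpha", "beta", "gamma"))
  if (length(bad)) stop("unknown band name(s) in band_amplitudes: ",
                        paste(bad, collapse = ", "))
  bands <- band_set()
  amp_hi <- max(vapply(coupling, function(cs) bands[[cs$amp_band]][2], 0),
                bands$gamma[2])
  if (fs <= 2 * amp_hi) {
    stop("fs = ", fs, " Hz too low: must exceed twice the highest ",
         "amplitude-band frequency (", amp_hi, " Hz)")
  }
  stopifnot(handedness_fraction_right >= 0, handedness_fraction_right <= 1)
  for (cs in coupling) stopifnot(inherits(cs, "coupling_spec"))
  structure(list(
    n_per_group = as.integer(n_per_group), fs = fs, duration_s = duration_s,
    electrodes = electrodes, seed = as.integer(seed),
    aperiodic_exponent = aperiodic_exponent, background_rms = background_rms,
    band_amplitudes = band_amplitudes, coupling = coupling,
    depth_sd = depth_sd,
    handedness_fraction_right = handedness_fraction_right,
    n_extra_channels = as.integer(n_extra_channels)
  ), class = "cohort_config")
}

#' Specify injected phase-amplitude coupling
#'
#' Coupling depth chi in `[0, 1]` is the fraction of the gamma-carrier
#' envelope modulated by the phase-band phase: the envelope is
#' `A * (1 - chi + chi * (1 + cos(phase)) / 2)`, which stays non-negative
#' for every chi.
#'
#' @param group `"control"` or `"als"`.
#' @param electrode Channel label; `"Cd"`/`"Cn"` are resolved per subject
#'   by handedness (Cd = C3 in right-handers, C4 in left-handers).
#' @param phase_band One of `"theta"`, `"alpha"`, `"beta"`.
#' @param depth Coupling depth chi in `[0, 1]`.
#' @param amp_band Amplitude band; only `"gamma"` is supported.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(group, electrode, phase_band, depth,
                          amp_band = "gamma") {
  group <- match.arg(group, c("control", "als"))
  phase_band <- match.arg(phase_band, c("theta", "alpha", "beta"))
  if (!identical(amp_band, "gamma")) {
    stop("amp_band must be 'gamma'")
  }
  stopifnot(is.numeric(depth), length(depth) == 1L, depth >= 0, depth <= 1)
  structure(list(group = group, electrode = electrode,
                 phase_band = phase_band, amp_band = amp_band,
                 depth = depth),
            class = "coupling_spec")
}

#' Default group coupling structure
#'
#' Mirrors the studied effect: theta-gamma coupling at the dominant central
#' electrode is reduced in the ALS group (control Cd depth 0.6, ALS Cd depth
#' 0.2) while the non-dominant electrode is equal across groups (0.35).
#'
#' @param control_cd,als_cd,cn Depths for the three coupled conditions.
#' @return List of [coupling_spec()] entries.
#' @export
default_coupling <- function(control_cd = 0.6, als_cd = 0.2, cn = 0.35) {
  list(
    coupling_spec("control", "Cd", "theta", control_cd),
    coupling_spec("als", "Cd", "theta", als_cd),
    coupling_spec("control", "Cn", "theta", cn),
    coupling_spec("als", "Cn", "theta", cn)
  )
}

# Resolve Cd/Cn coupling labels to physical electrodes for one subject.
resolve_couplings <- function(coupling, group, handedness) {
  out <- list()
  for (cs in coupling) {
    if (cs$group != group) next
    el <- cs$electrode
    if (el == "Cd") el <- if (handedness == "right") "C3" else "C4"
    if (el == "Cn") el <- if (handedness == "right") "C4" else "C3"
    cs$electrode <- el
    out[[length(out) + 1L]] <- cs
  }
  out
}

# Spectrally shaped Gaussian noise with power ~ 1/f^beta, scaled to target RMS.
colored_noise <- function(n, fs, beta, rms) {
  if (rms <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1L) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]  # mirror to physical frequency
  scale <- numeric(n)
  nz <- f > 0
  scale[nz] <- f[nz]^(-beta / 2)
  x <- Re(stats::fft(W * scale, inverse = TRUE) / n)
  x <- x - mean(x)
  x * rms / stats::sd(x)
}

band_center <- function(band) mean(band_set()[[band]])

#' Generate one synthetic EEG recording
#'
#' Signal model per channel: a 1/f^beta aperiodic background plus narrowband
#' oscillations (one per band with non-zero amplitude, with a small random
#' per-subject frequency jitter), plus a gamma carrier whose envelope is
#' modulated by the phase of the designated slow oscillation when a coupling
#' spec with depth chi > 0 applies to the channel:
#' `env(t) = A_gamma * (1 - chi + chi * (1 + cos(phase(t))) / 2)`.
#'
#' @param config A [cohort_config()].
#' @param group `"control"` or `"als"`.
#' @param handedness `"right"` or `"left"`.
#' @param subject_seed Integer seed; identical seed and config give a
#'   byte-identical recording.
#' @param subject_id Subject identifier string.
#' @return An object of class `eeg_recording` with fields `subject_id`,
#'   `group`, `handedness`, `fs`, `channel_labels`, `data` (channels x
#'   samples matrix, microvolts) and `bad_segments`.
#' @export
generate_subject_eeg <- function(config, group, handedness, subject_seed,
                                 subject_id = sprintf("%s_%03d",
                                                      group, subject_seed %% 1000L)) {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group, c("control", "als"))
  handedness <- match.arg(handedness, c("right", "left"))
  fs <- config$fs
  n <- round(fs * config$duration_s)
  t <- (seq_len(n) - 1L) / fs
  labels <- c(config$electrodes,
              if (config$n_extra_channels > 0)
                sprintf("E%d", seq_len(config$n_extra_channels)))
  couplings <- resolve_couplings(config$coupling, group, handedness)
  amps <- config$band_amplitudes

  with_seed(subject_seed, {
    # realized per-subject coupling depths (truncated normal around the
    # spec depth; specs at exactly 0 stay uncoupled)
    for (k in seq_along(couplings)) {
      cs <- couplings[[k]]
      if (cs$depth > 0 && config$depth_sd > 0) {
        v <- stats::rnorm(1, cs$depth, config$depth_sd)
        tries <- 0L
        while ((v < 0 || v > 1) && tries < 100L) {
          v <- stats::rnorm(1, cs$depth, config$depth_sd)
          tries <- tries + 1L
        }
        couplings[[k]]$depth <- min(1, max(0, v))
      }
    }
    data <- matrix(0, nrow = length(labels), ncol = n,
                   dimnames = list(labels, NULL))
    for (ci in seq_along(labels)) {
      el <- labels[ci]
      x <- colored_noise(n, fs, config$aperiodic_exponent,
                         config$background_rms)
      if (grepl("^E\\d+$", el)) {  # dummy channels: background only
        data[ci, ] <- x
        next
      }
      # slow oscillations with jittered frequency; keep each phase track
      phase_track <- list()
      for (b in c("theta", "alpha", "beta")) {
        f0 <- band_center(b) + stats::runif(1, -0.5, 0.5)
        ph0 <- stats::runif(1, 0, 2 * pi)
        phi <- 2 * pi * f0 * t + ph0
        phase_track[[b]] <- phi
        a <- if (b %in% names(amps)) amps[[b]] else 0
        # cosine convention: the analytic-signal phase of the emitted
        # oscillation equals phi, the phase that drives the coupling
        if (a > 0) x <- x + a * cos(phi)
      }
      # gamma carrier with (possibly) phase-modulated envelope
      fg <- band_center("gamma") + stats::runif(1, -1, 1)
      phg <- stats::runif(1, 0, 2 * pi)
      ag <- if ("gamma" %in% names(amps)) amps[["gamma"]] else 0
      env <- rep(ag, n)
      for (cs in couplings) {
        if (cs$electrode != el || cs$depth <= 0) next
        phi <- phase_track[[cs$phase_band]]
        env <- env * (1 - cs$depth + cs$depth * (1 + cos(phi)) / 2)
      }
      if (ag > 0) x <- x + env * cos(2 * pi * fg * t + phg)
      data[ci, ] <- x
    }
    structure(list(subject_id = subject_id, group = group,
                   handedness = handedness, fs = fs,
                   channel_labels = labels, data = data,
                   bad_segments = list(),
                   true_couplings = couplings),
              class = "eeg_recording")
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s  group=%s  handedness=%s\n",
              x$subject_id, x$group, x$handedness))
  cat(sprintf("  %d channels (%s) x %d samples @ %g Hz (%.1f s), %d bad segment(s)\n",
              nrow(x$data), paste(x$channel_labels, collapse = ", "),
              ncol(x$data), x$fs, ncol(x$data) / x$fs,
              length(x$bad_segments)))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Generates `2 * n_per_group` recordings (controls and ALS) with per-group
#' handedness assignment, plus a ground-truth manifest sufficient to
#' recompute which subject/electrode/pair carries coupling.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `recordings` (list of `eeg_recording`),
#'   `manifest` (data.frame: subject_id, group, handedness, seed) and
#'   `couplings` (data.frame of resolved true coupling depths per subject).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_per_group
  n_right <- round(config$handedness_fraction_right * n)
  recordings <- list()
  manifest <- list()
  coup_rows <- list()
  for (gi in 1:2) {
    group <- c("control", "als")[gi]
    for (i in seq_len(n)) {
      handedness <- if (i <= n_right) "right" else "left"
      seed_i <- child_seed(config$seed, gi, i)
      sid <- sprintf("%s_%02d", group, i)
      rec <- generate_subject_eeg(config, group, handedness, seed_i,
                                  subject_id = sid)
      recordings[[length(recordings) + 1L]] <- rec
      manifest[[length(manifest) + 1L]] <-
        data.frame(subject_id = sid, group = group,
                   handedness = handedness, seed = seed_i,
                   stringsAsFactors = FALSE)
      for (cs in rec$true_couplings) {
        coup_rows[[length(coup_rows) + 1L]] <-
          data.frame(subject_id = sid, electrode = cs$electrode,
                     phase_band = cs$phase_band, amp_band = cs$amp_band,
                     depth = cs$depth, stringsAsFactors = FALSE)
      }
    }
  }
  list(recordings = recordings,
       manifest = do.call(rbind, manifest),
       couplings = if (length(coup_rows)) do.call(rbind, coup_rows)
                   else data.frame())
}
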