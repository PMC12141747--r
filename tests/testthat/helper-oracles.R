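# Independent brute-force oracles, deliberately written with plain loops and
# kept apart from the package implementations they check.

# Modulation index by direct per-sample histogram accumulation.
oracle_mi <- function(phase, amp, n_bins) {
  ph <- ((phase + pi) %% (2 * pi)) - pi
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  width <- 2 * pi / n_bins
  for (i in seq_along(ph)) {
    b <- floor((ph[i] + pi) / width) + 1
    if (b > n_bins) b <- n_bins
    sums[b] <- sums[b] + amp[i]
    counts[b] <- counts[b] + 1L
  }
  mean_amp <- sums / counts
  P <- mean_amp / sum(mean_amp)
  H <- 0
  for (p in P) if (p > 0) H <- H - p * log(p)
  (log(n_bins) - H) / log(n_bins)
}

# AUC by exhaustive positive-negative pair comparison (ties count 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Pearson chi-square by the textbook sum over cells.
oracle_chi2 <- function(tab) {
  n <- sum(tab)
  chi2 <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      chi2 <- chi2 + (tab[i, j] - e)^2 / e
    }
  }
  chi2
}

# Construct a phase/amp pair whose binned amplitude distribution is exactly
# the given P over n_bins (dense uniform phase coverage).
series_with_P <- function(P, n_bins, per_bin = 50) {
  centers <- -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  phase <- rep(centers, each = per_bin) +
    rep(seq(-0.4, 0.4, length.out = per_bin) * 2 * pi / n_bins, n_bins)
  amp <- rep(P, each = per_bin)
  list(phase = phase, amp = amp)
}

# A minimal eeg_recording wrapper around a plain matrix.
make_recording <- function(data, fs, labels = paste0("ch", seq_len(nrow(data))),
                           group = "control", handedness = "right",
                           subject_id = "s1") {
  structure(list(subject_id = subject_id, group = group,
                 handedness = handedness, fs = fs,
                 channel_labels = labels,
                 data = matrix(data, nrow = length(labels),
                               dimnames = list(labels, NULL)),
                 bad_segments = list()),
            class = "eeg_recording")
}
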