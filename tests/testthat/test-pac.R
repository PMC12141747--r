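test_that("modulation index reproduces the analytic reference cases", {
  ph <- seq(-pi, pi - 1e-9, length.out = 3600)
  # amplitude independent of phase -> uniform P -> MI = 0
  expect_equal(modulation_index(ph, rep(2, 3600))$MI, 0, tolerance = 1e-12)
  # all amplitude mass in one bin -> H = 0 -> MI = 1
  one_bin <- as.numeric(ph < -pi + 2 * pi / 18)
  expect_equal(modulation_index(ph, one_bin)$MI, 1, tolerance = 1e-12)
  # N = 4, P = (1/2, 1/2, 0, 0) -> MI = (log 4 - log 2)/log 4 = 0.5
  half <- as.numeric(ph < 0)
  expect_equal(modulation_index(ph, half, 4)$MI, 0.5, tolerance = 1e-12)
})

test_that("modulation index equals the brute-force histogram oracle", {
  # deterministic cosine-modulated envelope
  ph <- seq(-pi, pi - 1e-9, length.out = 5000)
  amp <- 1 + cos(ph)
  expect_equal(modulation_index(ph, amp, 18)$MI, oracle_mi(ph, amp, 18),
               tolerance = 1e-12)
  # 50 random fixtures with varying N and skewed amplitude laws
  withr::with_seed(10, {
    for (i in 1:50) {
      N <- sample(c(8L, 12L, 18L, 24L), 1)
      n <- 10 * N + sample(0:500, 1)
      phase <- runif(n, -pi, pi)
      amp <- rexp(n) * (1 + 0.8 * cos(phase + runif(1, -pi, pi)))
      expect_equal(modulation_index(phase, amp, N)$MI,
                   oracle_mi(phase, amp, N), tolerance = 1e-12)
    }
  })
})

test_that("modulation index is invariant to amplitude rescaling", {
  withr::with_seed(11, {
    phase <- runif(4000, -pi, pi)
    amp <- rexp(4000) * (1 + 0.5 * cos(phase))
  })
  m1 <- modulation_index(phase, amp)$MI
  m2 <- modulation_index(phase, 1234.5 * amp)$MI
  expect_equal(m1, m2, tolerance = 1e-12)
  expect_gte(m1, 0)
  expect_lte(m1, 1)
})

test_that("degenerate modulation-index inputs raise the contracted errors", {
  ph <- seq(-pi, pi - 1e-9, length.out = 400)
  expect_error(modulation_index(ph, rep(0, 400)), "all zero")
  expect_error(modulation_index(ph[1:100], rep(1, 100), 18), "too short")
  expect_error(modulation_index(ph, rep(1, 399)), "equal length")
  # phases confined to half the circle -> empty bins
  expect_error(modulation_index(abs(ph), rep(1, 400), 18),
               "insufficient phase coverage")
})

test_that("extract_phase_amp recovers phase progression of a pure tone", {
  fs <- 250
  t <- (seq_len(fs * 30) - 1) / fs
  pa <- extract_phase_amp(sin(2 * pi * 6 * t), fs, c(4, 8), c(30, 60))
  dph <- diff(pa$phase)
  dph <- ((dph + pi) %% (2 * pi)) - pi
  expect_lt(sqrt(mean((dph - 2 * pi * 6 / fs)^2)), 1e-3)
})

test_that("full-depth coupling is visible in the extracted envelope", {
  cfg <- cohort_config(n_per_group = 2, fs = 250, duration_s = 30, seed = 1,
                       depth_sd = 0, background_rms = 0.1,
                       coupling = list(coupling_spec("control", "C3",
                                                     "theta", 1)))
  rec <- generate_subject_eeg(cfg, "control", "right", 21)
  pa <- extract_phase_amp(rec$data["C3", ], cfg$fs, c(4, 8), c(30, 60))
  expect_gt(cor(pa$amp, (1 + cos(pa$phase)) / 2), 0.95)
})

test_that("band limits and sampling rates are validated", {
  x <- rnorm(2000)
  expect_error(extract_phase_amp(x, 100, c(4, 8), c(30, 60)), "too low")
  expect_error(extract_phase_amp(x, 250, c(1, 3), c(30, 60)), "band-pass")
})

test_that("comodulogram localizes injected theta-gamma coupling", {
  cfg <- cohort_config(n_per_group = 2, fs = 250, duration_s = 40, seed = 1,
                       depth_sd = 0,
                       coupling = list(coupling_spec("control", "C3",
                                                     "theta", 0.8)))
  rec <- generate_subject_eeg(cfg, "control", "right", 31)
  x <- rec$data["C3", ]
  com <- comodulogram(x, cfg$fs)
  expect_true(all(com$mi >= 0 & com$mi <= 1))
  peak <- which(com$mi == max(com$mi), arr.ind = TRUE)
  expect_true(com$grid$phase_axis[peak[1]] >= 4 &&
                com$grid$phase_axis[peak[1]] < 8)
  expect_true(com$grid$amp_axis[peak[2]] >= 30 &&
                com$grid$amp_axis[peak[2]] < 60)
  # determinism: identical signal, identical map
  expect_identical(com$mi, comodulogram(x, cfg$fs)$mi)
})

test_that("uncoupled noise never beats its own time-shift surrogate", {
  fs <- 250
  withr::with_seed(2, x <- rnorm(fs * 40))
  grid <- pac_grid()
  com <- comodulogram(x, fs, grid)
  # surrogate: circular shifts (>= 1 s) of every amplitude series against
  # fixed phases, max over the map per shift
  trim <- fs
  n <- length(x)
  keep <- rep(TRUE, n)
  keep[c(seq_len(trim), (n - trim + 1L):n)] <- FALSE
  idx <- which(keep)
  phases <- lapply(grid$phase_axis, function(f0)
    Arg(thetapac:::band_analytic(x, fs, f0 - 1, f0 + 1))[idx])
  amps <- lapply(grid$amp_axis, function(f0)
    Mod(thetapac:::band_analytic(x, fs, f0 - 5, f0 + 5))[idx])
  withr::with_seed(2, {
    lags <- sample(seq(fs, length(idx) - fs), 200, replace = TRUE)
    max_null <- vapply(lags, function(L) {
      m <- 0
      for (pp in phases) {
        for (aa in amps) {
          aa_s <- c(aa[(L + 1):length(aa)], aa[1:L])
          m <- max(m, modulation_index(pp, aa_s)$MI)
        }
      }
      m
    }, 0)
  })
  expect_lt(max(com$mi), quantile(max_null, 0.99))
})

test_that("mean_mi averages exactly over the pair region", {
  grid <- pac_grid()
  com <- structure(list(grid = grid,
                        mi = matrix(0.37, length(grid$phase_axis),
                                    length(grid$amp_axis)),
                        n_phase_bins = 18L), class = "comodulogram")
  for (pair in pac_pairs()) {
    expect_equal(mean_mi(com, pair), 0.37)
  }
  # support only inside theta x gamma -> other pairs exactly zero
  com$mi[] <- 0
  theta_cells <- in_band(grid$phase_axis, c(4, 8))
  com$mi[theta_cells, ] <- 0.5
  expect_gt(mean_mi(com, "theta-gamma"), 0)
  expect_equal(mean_mi(com, "alpha-gamma"), 0)
  expect_equal(mean_mi(com, "beta-gamma"), 0)
})

test_that("fine grid spans 100 centers per axis", {
  g <- pac_grid(fine = TRUE)
  expect_length(g$phase_axis, 100)
  expect_length(g$amp_axis, 100)
  expect_true(min(g$phase_axis) >= 2 && max(g$phase_axis) <= 30)
  expect_true(min(g$amp_axis) >= 30 && max(g$amp_axis) <= 60)
})

test_that("pac_table recodes electrodes and covers all pairs", {
  cfg <- cohort_config(n_per_group = 2, fs = 250, duration_s = 20, seed = 3,
                       handedness_fraction_right = 0.5)
  coh <- generate_cohort(cfg)
  recs <- lapply(coh$recordings, preprocess,
                 cfg = preprocess_config(target_fs = 250, min_clean_s = 10))
  tab <- pac_table(recs, grid = band_grid())
  expect_equal(nrow(tab), length(recs) * 5 * 3)
  expect_setequal(unique(tab$electrode), c("Cd", "Cn", "Cz", "Fz", "Pz"))
  expect_true(all(tab$mean_mi >= 0 & tab$mean_mi <= 1))
})
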