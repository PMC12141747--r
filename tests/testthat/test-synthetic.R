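test_that("subject generator is a pure function of its seed", {
  cfg <- cohort_config(n_per_group = 2, fs = 250, duration_s = 10, seed = 1)
  r1 <- generate_subject_eeg(cfg, "als", "right", 99)
  r2 <- generate_subject_eeg(cfg, "als", "right", 99)
  expect_identical(r1$data, r2$data)
  r3 <- generate_subject_eeg(cfg, "als", "right", 100)
  expect_false(identical(r1$data, r3$data))
})

test_that("generator validates configuration", {
  expect_error(cohort_config(n_per_group = 1), "n_per_group")
  expect_error(cohort_config(fs = 100), "fs")
  expect_error(cohort_config(band_amplitudes = c(delta = 1)), "unknown band")
  expect_error(coupling_spec("control", "C3", "gamma", 0.5))
  expect_error(coupling_spec("control", "C3", "theta", 1.5))
  expect_error(coupling_spec("control", "C3", "theta", 0.5,
                             amp_band = "beta"), "gamma")
})

test_that("cohort manifest counts groups and forced handedness", {
  cfg <- cohort_config(n_per_group = 2, fs = 250, duration_s = 5, seed = 4,
                       handedness_fraction_right = 1.0)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$manifest), 4L)
  expect_equal(as.integer(table(coh$manifest$group)), c(2L, 2L))
  expect_true(all(coh$manifest$handedness == "right"))
  # ground truth sufficient to locate coupling: default spec puts
  # theta-gamma on C3 (Cd) and C4 (Cn) for right-handers
  expect_setequal(unique(coh$couplings$electrode), c("C3", "C4"))
  expect_true(all(coh$couplings$phase_band == "theta"))
})

test_that("injected coupling is detectable where and only where injected", {
  # chi = 0.8 theta->gamma at C3 only; MI at C3 theta-gamma must exceed the
  # other pairs by > 5 surrogate-null standard deviations (time-shift null)
  cfg <- cohort_config(n_per_group = 2, fs = 250, duration_s = 60, seed = 1,
                       depth_sd = 0,
                       coupling = list(coupling_spec("control", "C3",
                                                     "theta", 0.8)))
  n_subj <- 20
  shifts <- 200
  mi_tg <- mi_ag <- mi_bg <- numeric(n_subj)
  null_sd <- numeric(n_subj)
  withr::with_seed(1, {
    for (s in seq_len(n_subj)) {
      rec <- generate_subject_eeg(cfg, "control", "right", 1000 + s)
      x <- rec$data["C3", ]
      pa <- extract_phase_amp(x, cfg$fs, c(4, 8), c(30, 60))
      mi_tg[s] <- modulation_index(pa$phase, pa$amp)$MI
      pa2 <- extract_phase_amp(x, cfg$fs, c(8, 13), c(30, 60))
      mi_ag[s] <- modulation_index(pa2$phase, pa2$amp)$MI
      pa3 <- extract_phase_amp(x, cfg$fs, c(13, 30), c(30, 60))
      mi_bg[s] <- modulation_index(pa3$phase, pa3$amp)$MI
      lag <- sample(seq(cfg$fs, length(pa$amp) - cfg$fs), shifts,
                    replace = TRUE)
      null_mi <- vapply(lag, function(L) {
        amp_s <- c(pa$amp[(L + 1):length(pa$amp)], pa$amp[1:L])
        modulation_index(pa$phase, amp_s)$MI
      }, 0)
      null_sd[s] <- sd(null_mi)
    }
  })
  expect_gt(mean(mi_tg) - mean(mi_ag), 5 * mean(null_sd))
  expect_gt(mean(mi_tg) - mean(mi_bg), 5 * mean(null_sd))
})

test_that("uncoupled cohorts look like the time-shift surrogate null", {
  cfg <- cohort_config(n_per_group = 2, fs = 250, duration_s = 20, seed = 2,
                       coupling = list())
  n_subj <- 20
  inside <- logical(n_subj)
  withr::with_seed(2, {
    for (s in seq_len(n_subj)) {
      rec <- generate_subject_eeg(cfg, "control", "right", 2000 + s)
      pa <- extract_phase_amp(rec$data["C3", ], cfg$fs, c(4, 8), c(30, 60))
      mi <- modulation_index(pa$phase, pa$amp)$MI
      lag <- sample(seq(cfg$fs, length(pa$amp) - cfg$fs), 100,
                    replace = TRUE)
      null_mi <- vapply(lag, function(L) {
        amp_s <- c(pa$amp[(L + 1):length(pa$amp)], pa$amp[1:L])
        modulation_index(pa$phase, amp_s)$MI
      }, 0)
      qs <- quantile(null_mi, c(0.025, 0.975))
      inside[s] <- mi >= qs[1] && mi <= qs[2]
    }
  })
  expect_gte(mean(inside), 0.85)
})

test_that("modulation index grows monotonically with coupling depth", {
  mis <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(chi) {
    cfg <- cohort_config(n_per_group = 2, fs = 250, duration_s = 30,
                         seed = 1, background_rms = 1e-3, depth_sd = 0,
                         band_amplitudes = c(theta = 5, alpha = 0, beta = 0,
                                             gamma = 2),
                         coupling = list(coupling_spec("control", "C3",
                                                       "theta", chi)))
    rec <- generate_subject_eeg(cfg, "control", "right", 7)
    pa <- extract_phase_amp(rec$data["C3", ], cfg$fs, c(4, 8), c(30, 60))
    modulation_index(pa$phase, pa$amp)$MI
  }, 0)
  expect_true(all(diff(mis) > 0))
})

test_that("clinical table generator is deterministic and in range", {
  t1 <- generate_clinical_table(10, seed = 7)
  t2 <- generate_clinical_table(10, seed = 7)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 10L)
  expect_true(all(t1$alsfrs_r >= 0 & t1$alsfrs_r <= 48))
  expect_true(all(t1$ecas_total >= 0 & t1$ecas_total <= 136, na.rm = TRUE))
  expect_true(all(t1$duration_months > 0))
})

test_that("DTI generator: row counts, forced zero asymmetry, determinism", {
  d <- generate_dti_table(3, seed = 5)
  expect_equal(nrow(d), 48L)  # 3 x 2 groups x 2 hemispheres x 4 levels
  expect_true(all(d$FA >= 0 & d$FA <= 1))
  expect_true(all(d$AD > 0 & d$RD > 0))
  expect_identical(d, generate_dti_table(3, seed = 5))
  # zero offsets and zero noise -> exact zero deltas
  z <- generate_dti_table(2, seed = 1,
                          asymmetry_spec = default_dti_asymmetry()[0, ],
                          noise_sd = list(FA = 0, AD = 0, RD = 0))
  a <- asymmetry_table(z)
  expect_true(all(a$delta == 0))
})
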