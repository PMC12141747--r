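test_that("IQR screening flags exactly the gross outlier", {
  d <- data.frame(v = c(1:9, 100))
  rep_ <- iqr_outliers(d, "v")
  expect_equal(rep_$flags$v, 100)
  # fences from the linear-interpolation quantile convention
  q <- quantile(d$v, c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(rep_$fences$lower, q[1] - 1.5 * diff(q))
  expect_equal(rep_$fences$upper, q[2] + 1.5 * diff(q))
})

test_that("IQR screening: degenerate and per-cell behaviour", {
  all_eq <- data.frame(v = rep(5, 8))
  expect_equal(nrow(iqr_outliers(all_eq, "v")$flags), 0L)
  sym <- data.frame(v = c(-2, -1, -1, 0, 0, 0, 1, 1, 2))
  expect_equal(nrow(iqr_outliers(sym, "v")$flags), 0L)
  # per-cell screening: an outlier in one cell is invisible to the other
  d <- data.frame(v = c(1:7, 50, 101:107, 104),
                  g = rep(c("a", "b"), each = 8))
  rep_ <- iqr_outliers(d, "v", by = "g")
  expect_equal(rep_$flags$v, 50)
  expect_warning(iqr_outliers(data.frame(v = 1:3), "v"), "fewer than 4")
})

test_that("Cohen's d matches hand-computed cases", {
  expect_equal(cohens_d(c(0, 1, 2), c(2, 3, 4)), -2)
  expect_equal(cohens_d(c(5, 6, 7), c(5, 6, 7)), 0)
  expect_error(cohens_d(rep(1, 3), rep(1, 3)), "zero")
  # affine invariance: d(a*x+b) = d(x) for positive a
  withr::with_seed(1, {
    a <- rnorm(20); b <- rnorm(20, 1)
  })
  expect_equal(cohens_d(3 * a + 7, 3 * b + 7), cohens_d(a, b),
               tolerance = 1e-12)
})

test_that("Pearson correlation: exact lines and affine equivariance", {
  x <- c(1, 2, 4, 7, 11)
  r1 <- pearson_corr(x, 2 * x + 1)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  r2 <- pearson_corr(x, -x)
  expect_equal(r2$r, -1, tolerance = 1e-12)
  withr::with_seed(2, {
    u <- rnorm(30); v <- u + rnorm(30)
  })
  expect_equal(pearson_corr(u, v)$r, pearson_corr(5 * u - 2, 0.1 * v + 4)$r,
               tolerance = 1e-12)
  expect_equal(pearson_corr(u, v)$r, -pearson_corr(u, -v)$r,
               tolerance = 1e-12)
  expect_error(pearson_corr(u, rep(1, 30)), "zero variance")
  expect_error(pearson_corr(1:3, 3:1), "at least 4")
})

test_that("Pearson CI has near-nominal coverage at rho = 0.5", {
  n <- 24
  rho <- 0.5
  withr::with_seed(42, {
    res <- replicate(1000, {
      x <- rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      pc <- pearson_corr(x, y)
      c(pc$r, pc$ci[1] <= rho && rho <= pc$ci[2])
    })
  })
  expect_lt(abs(mean(res[1, ]) - rho), 0.05)
  expect_lt(abs(mean(res[2, ]) - 0.95), 0.02)
})

test_that("two-group design reduces to the pooled t-test (F = t^2)", {
  withr::with_seed(3, {
    d <- data.frame(subject_id = sprintf("s%02d", 1:20),
                    group = rep(c("a", "b"), each = 10),
                    y = c(rnorm(10), rnorm(10, 0.8)))
  })
  m <- fit_rm_lmm(d, y ~ group)
  expect_true(m$used_lm)
  tt <- t.test(y ~ group, data = d, var.equal = TRUE)
  expect_equal(m$fixed_tests$F[m$fixed_tests$term == "group"],
               unname(tt$statistic)^2, tolerance = 1e-6)
})

test_that("marginal means of a balanced design equal cell means", {
  withr::with_seed(4, {
    d <- expand.grid(subject_id = sprintf("s%02d", 1:12),
                     cond = c("x", "y", "z"), stringsAsFactors = FALSE)
    d$y <- rnorm(nrow(d)) + ifelse(d$cond == "y", 1, 0)
  })
  m <- fit_rm_lmm(d, y ~ cond)
  mm <- marginal_means(m, "cond")
  cell <- tapply(d$y, d$cond, mean)
  expect_equal(as.numeric(mm$emmean),
               as.numeric(cell[as.character(mm$cond)]),
               tolerance = 1e-9)
})

test_that("singular random-slope fits fall back to intercept-only", {
  withr::with_seed(5, {
    d <- expand.grid(subject_id = sprintf("s%02d", 1:16),
                     cond = c("x", "y"), stringsAsFactors = FALSE)
    re <- rnorm(16, 0, 1)
    names(re) <- sprintf("s%02d", 1:16)
    d$y <- re[d$subject_id] + rnorm(nrow(d), 0, 0.5)  # no slope variance
  })
  m <- fit_rm_lmm(d, y ~ cond, slope_factor = "cond")
  expect_true(m$refitted_intercept_only || !m$singular)
  expect_true(all(is.finite(m$fixed_tests$F)))
})

test_that("constant responses are refused", {
  d <- data.frame(subject_id = rep(sprintf("s%d", 1:4), 2),
                  g = rep(c("a", "b"), 4), y = 1)
  expect_error(fit_rm_lmm(d, y ~ g), "zero variance")
})

test_that("mixed-model F-test p agrees with a permutation test under the null", {
  withr::with_seed(6, {
    d <- expand.grid(subject_id = sprintf("s%02d", 1:12),
                     cond = c("x", "y", "z"), stringsAsFactors = FALSE)
    d$group <- ifelse(as.integer(sub("s", "", d$subject_id)) <= 6,
                      "a", "b")
    re <- rnorm(12, 0, 0.7)
    names(re) <- sprintf("s%02d", 1:12)
    d$y <- re[d$subject_id] + rnorm(nrow(d))
  })
  m <- fit_rm_lmm(d, y ~ group * cond)
  p_obs <- m$fixed_tests$p[m$fixed_tests$term == "group"]
  # permutation of group labels at the subject level
  withr::with_seed(7, {
    subj <- unique(d$subject_id)
    f_obs <- m$fixed_tests$F[m$fixed_tests$term == "group"]
    f_perm <- replicate(200, {
      g <- setNames(sample(rep(c("a", "b"), each = 6)), subj)
      d2 <- d
      d2$group <- g[d2$subject_id]
      m2 <- fit_rm_lmm(d2, y ~ group * cond)
      m2$fixed_tests$F[m2$fixed_tests$term == "group"]
    })
  })
  p_perm <- mean(f_perm >= f_obs)
  expect_lt(abs(p_obs - p_perm), 0.12)
})

test_that("f2 is near zero for a null term and positive for a real effect", {
  withr::with_seed(8, {
    d <- expand.grid(subject_id = sprintf("s%02d", 1:20),
                     cond = c("x", "y"), stringsAsFactors = FALSE)
    d$group <- ifelse(as.integer(sub("s", "", d$subject_id)) <= 10,
                      "a", "b")
    d$y <- rnorm(nrow(d), 0, 0.3) + ifelse(d$cond == "y", 2, 0)
  })
  m <- fit_rm_lmm(d, y ~ group + cond)
  expect_gt(effect_f2(m, "cond"), 0.5)
  expect_lt(abs(effect_f2(m, "group")), 0.1)
})

test_that("group contrast recovers the calibrated effect size", {
  # synthetic Cd theta-gamma cohorts at the default depths: the recovered
  # |d| should sit near the generator's calibration target (~1.13) at the
  # full 300-s / 400-Hz study scale
  ds <- vapply(1:4, function(r) {
    n <- 26
    mi <- vapply(seq_len(2 * n), function(i) {
      grp <- if (i <= n) "control" else "als"
      depth <- if (i <= n) 0.6 else 0.2
      cfg <- cohort_config(n_per_group = 2, fs = 400, duration_s = 300,
                           seed = 1,
                           coupling = list(coupling_spec(grp, "C3",
                                                         "theta", depth)))
      rec <- generate_subject_eeg(cfg, grp, "right",
                                  thetapac:::child_seed(50, r, i))
      pa <- extract_phase_amp(rec$data["C3", ], 400, c(4, 8), c(30, 60))
      modulation_index(pa$phase, pa$amp)$MI
    }, 0)
    cohens_d(mi[1:n], mi[(n + 1):(2 * n)])
  }, 0)
  expect_lt(abs(mean(ds) - 1.13), 0.45)
  expect_true(all(ds > 0))
})
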