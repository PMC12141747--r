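# Seeded Monte-Carlo study helpers used for recovery, specificity,
# calibration and ordering experiments. Replicate studies keep the cohort
# sizes of the emulated study but use shortened recordings (see the methods
# vignette for the rationale on problem sizes).

#' Coupling-recovery and specificity study
#'
#' For each replicate: generate a two-group cohort with the default
#' coupling structure (theta-gamma reduced at Cd in the ALS group, Cn equal
#' across groups), preprocess, summarize PAC per electrode and pair
#' (band-level grid), and test the group contrast in every electrode x
#' pair cell with a Student t-test. Recovery = the Cd theta-gamma contrast
#' has the injected sign (control > ALS); specificity = every other cell is
#' non-significant at `alpha`.
#'
#' @param n_rep Number of replicates (default 100).
#' @param n_per_group Subjects per group per replicate (default 26).
#' @param seed Master seed.
#' @param fs,duration_s Recording scale per replicate (defaults 250 Hz,
#'   20 s: shortened from the 400 Hz / 300 s study conditions to keep the
#'   study tractable; generator defaults are unchanged).
#' @param alpha Test level (default 0.05).
#' @param coupling Coupling structure (default [default_coupling()]).
#' @return List: `cells` (data.frame rep x electrode x pair with diff and
#'   p), `cd_sign_rate`, `cd_sig_rate`, `specificity_rate` (fraction of
#'   replicates with all off-target cells non-significant),
#'   `offtarget_nonsig_rate` (per-cell), `cohens_d_cd` (mean across reps).
#' @export
coupling_recovery_study <- function(n_rep = 100L, n_per_group = 26L,
                                    seed = 1L, fs = 250, duration_s = 20,
                                    alpha = 0.05,
                                    coupling = default_coupling()) {
  rows <- list()
  d_cd <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- cohort_config(n_per_group = n_per_group, fs = fs,
                         duration_s = duration_s,
                         seed = child_seed(seed, 7L, r),
                         coupling = coupling)
    coh <- generate_cohort(cfg)
    pcfg <- preprocess_config(target_fs = fs,
                              min_clean_s = duration_s * 0.5)
    recs <- lapply(coh$recordings, preprocess, cfg = pcfg)
    tab <- pac_table(recs, grid = band_grid())
    for (el in unique(tab$electrode)) {
      for (pr in unique(tab$pair)) {
        cell <- tab[tab$electrode == el & tab$pair == pr, ]
        a <- cell$mean_mi[cell$group == "control"]
        b <- cell$mean_mi[cell$group == "als"]
        tt <- stats::t.test(a, b, var.equal = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          rep = r, electrode = el, pair = pr, diff = mean(a) - mean(b),
          p = tt$p.value, stringsAsFactors = FALSE)
        if (el == "Cd" && pr == "theta-gamma") d_cd[r] <- cohens_d(a, b)
      }
    }
  }
  cells <- do.call(rbind, rows)
  cd <- cells[cells$electrode == "Cd" & cells$pair == "theta-gamma", ]
  off <- cells[!(cells$electrode == "Cd" & cells$pair == "theta-gamma"), ]
  spec_by_rep <- tapply(off$p > alpha, off$rep, all)
  per_cell <- stats::aggregate(p ~ electrode + pair, data = off,
                               FUN = function(p) mean(p > alpha))
  names(per_cell)[names(per_cell) == "p"] <- "nonsig_rate"
  list(cells = cells,
       cd_sign_rate = mean(cd$diff > 0),
       cd_sig_rate = mean(cd$p < alpha & cd$diff > 0),
       specificity_rate = mean(spec_by_rep),
       offtarget_nonsig_rate = mean(off$p > alpha),
       per_cell_nonsig = per_cell,
       min_cell_nonsig_rate = min(per_cell$nonsig_rate),
       cohens_d_cd = mean(d_cd))
}

#' Null-calibration study for the repeated-measures group tests
#'
#' Generates long summary tables with no group difference (subject random
#' intercept plus residual noise over the within-subject cells), fits the
#' repeated-measures mixed model and records the group F-test p-value and
#' the Cd target-cell post hoc t-test p-value per replicate. Under the
#' null both should reject at close to the nominal level.
#'
#' @param n_rep Replicates (default 100).
#' @param n_per_group Subjects per group (default 26).
#' @param seed Master seed.
#' @param type `"pac"` (electrode x frequency-pair cells, target cell Cd
#'   theta-gamma) or `"power"` (electrode x band cells, target Cd alpha).
#' @param alpha Test level.
#' @param subject_sd,noise_sd Random-intercept and residual SDs.
#' @return List: `p_group` and `p_target` vectors, `group_rejection_rate`,
#'   `target_rejection_rate`.
#' @export
null_calibration_study <- function(n_rep = 100L, n_per_group = 26L,
                                   seed = 1L, type = c("pac", "power"),
                                   alpha = 0.05, subject_sd = 0.5,
                                   noise_sd = 1) {
  type <- match.arg(type)
  electrodes <- c("Cd", "Cn", "Cz", "Fz", "Pz")
  within <- if (type == "pac") pac_pairs()
            else c("theta", "alpha", "beta", "gamma")
  within_name <- if (type == "pac") "pair" else "band"
  target_within <- if (type == "pac") "theta-gamma" else "alpha"
  p_group <- p_target <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    dat <- with_seed(child_seed(seed, 11L, r), {
      grid <- expand.grid(subject_id = sprintf("s%02d", seq_len(2 * n_per_group)),
                          electrode = electrodes, w = within,
                          stringsAsFactors = FALSE)
      grid$group <- ifelse(as.integer(sub("s", "", grid$subject_id)) <=
                             n_per_group, "control", "als")
      re <- stats::rnorm(2 * n_per_group, 0, subject_sd)
      names(re) <- sprintf("s%02d", seq_len(2 * n_per_group))
      grid$value <- re[grid$subject_id] +
        stats::rnorm(nrow(grid), 0, noise_sd)
      names(grid)[names(grid) == "w"] <- within_name
      grid
    })
    fml <- stats::as.formula(paste("value ~ group * electrode *", within_name))
    m <- fit_rm_lmm(dat, fml, subject = "subject_id")
    p_group[r] <- m$fixed_tests$p[m$fixed_tests$term == "group"]
    cell <- dat[dat$electrode == "Cd" & dat[[within_name]] == target_within, ]
    tt <- stats::t.test(value ~ group, data = cell, var.equal = TRUE)
    p_target[r] <- tt$p.value
  }
  list(p_group = p_group, p_target = p_target,
       group_rejection_rate = mean(p_group < alpha),
       target_rejection_rate = mean(p_target < alpha))
}

#' ROC ordering study: combined versus single markers
#'
#' Per replicate, draws a strong marker and a weak independent marker
#' (Gaussian location shifts calibrated to the requested single-marker
#' AUCs), combines them by logistic regression and records whether the
#' combined score's AUC is at least the best single-marker AUC.
#'
#' @param n_rep Replicates (default 100).
#' @param n_per_group Subjects per group (default 100: large enough that
#'   the in-sample noise of the two-parameter logistic fit does not mask
#'   the population ordering, which separates the combined AUC from the
#'   strong marker by only ~0.015).
#' @param seed Master seed.
#' @param auc_strong,auc_weak Population AUCs of the two markers
#'   (defaults 0.86 and 0.64, the strong-EEG / weak-DTI regime).
#' @return List: `auc` (data.frame of single and combined AUCs per rep),
#'   `combined_ge_best_rate`, `mean_auc_strong`, `mean_auc_weak`,
#'   `mean_auc_combined`.
#' @export
roc_ordering_study <- function(n_rep = 100L, n_per_group = 100L, seed = 1L,
                               auc_strong = 0.86, auc_weak = 0.64) {
  d_s <- sqrt(2) * stats::qnorm(auc_strong)
  d_w <- sqrt(2) * stats::qnorm(auc_weak)
  rows <- lapply(seq_len(n_rep), function(r) {
    with_seed(child_seed(seed, 13L, r), {
      labels <- rep(c(FALSE, TRUE), each = n_per_group)
      strong <- stats::rnorm(2 * n_per_group) + d_s * labels
      weak <- stats::rnorm(2 * n_per_group) + d_w * labels
      comb <- combine_predictors(data.frame(strong = strong, weak = weak),
                                 labels, n_boot = 0L)
      data.frame(rep = r,
                 auc_strong = rank_auc(strong, labels),
                 auc_weak = rank_auc(weak, labels),
                 auc_combined = comb$roc$auc)
    })
  })
  auc <- do.call(rbind, rows)
  list(auc = auc,
       combined_ge_best_rate =
         mean(auc$auc_combined >= pmax(auc$auc_strong, auc$auc_weak)),
       mean_auc_strong = mean(auc$auc_strong),
       mean_auc_weak = mean(auc$auc_weak),
       mean_auc_combined = mean(auc$auc_combined))
}

#' Permutation null for the AUC
#'
#' Mean rank-AUC over label permutations of a fixed score vector; should
#' center on 0.5.
#'
#' @param n Total sample size (half per class).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed.
#' @return List: `mean_auc`, `aucs`.
#' @export
auc_permutation_null <- function(n = 52L, n_perm = 1000L, seed = 1L) {
  with_seed(seed, {
    scores <- stats::rnorm(n)
    labels <- rep(c(TRUE, FALSE), length.out = n)
    aucs <- vapply(seq_len(n_perm), function(i) {
      rank_auc(scores, sample(labels))
    }, 0)
    list(mean_auc = mean(aucs), aucs = aucs)
  })
}

#' DTI asymmetry detection study
#'
#' Per replicate, generates a synthetic DTI table with the default
#' caudal-only asymmetry, computes per-subject dominant-minus-nondominant
#' FA deltas and tests, per level, whether the pooled asymmetry differs
#' from zero (one-sample t) and whether the group difference in delta has
#' the injected sign (control > ALS at the caudal levels).
#'
#' @param n_rep Replicates (default 100).
#' @param n_per_group Subjects per group (default 25).
#' @param seed Master seed.
#' @param alpha Test level.
#' @return List: `levels` (data.frame rep x level with p_asym and group
#'   diff), `per_level` (detection rate per level),
#'   `caudal_detection_rate` (worst caudal per-level detection rate),
#'   `rostral_nonsig_rate` (worst rostral per-level non-significance rate),
#'   `group_sign_rate_brainstem`, `group_sig_rate_brainstem`.
#' @export
dti_asymmetry_study <- function(n_rep = 100L, n_per_group = 25L, seed = 1L,
                                alpha = 0.05) {
  rows <- list()
  for (r in seq_len(n_rep)) {
    dti <- generate_dti_table(n_per_group, seed = child_seed(seed, 17L, r))
    asym <- asymmetry_table(dti)
    fa <- asym[asym$metric == "FA", ]
    for (lev in dti_levels()) {
      cell <- fa[fa$level == lev, ]
      tt <- stats::t.test(cell$delta)
      a <- cell$delta[cell$group == "control"]
      b <- cell$delta[cell$group == "als"]
      gt <- stats::t.test(a, b, var.equal = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, level = lev, p_asym = tt$p.value,
        group_diff = mean(a) - mean(b), p_group = gt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  levels_df <- do.call(rbind, rows)
  per_level <- stats::aggregate(p_asym ~ level, data = levels_df,
                                FUN = function(p) mean(p < alpha))
  names(per_level)[2] <- "detection_rate"
  rate_of <- function(lev) per_level$detection_rate[per_level$level == lev]
  bs <- levels_df[levels_df$level == "Brainstem", ]
  list(levels = levels_df,
       per_level = per_level,
       caudal_detection_rate = min(rate_of("Peduncle"), rate_of("Brainstem")),
       rostral_nonsig_rate = 1 - max(rate_of("s.Cortex"), rate_of("i.Capsule")),
       group_sign_rate_brainstem = mean(bs$group_diff > 0),
       group_sig_rate_brainstem = mean(bs$p_group < alpha))
}
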