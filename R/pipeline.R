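#' Build a pipeline run configuration
#'
#' Bundles the per-stage configurations for an end-to-end run: simulate (or
#' load) a cohort, preprocess, band powers, PAC summaries, cohort
#' statistics, clinical phenotyping, DTI asymmetry and ROC stratification.
#'
#' @param out_dir Output directory for the results bundle.
#' @param seed Master seed; every stage derives its randomness from it.
#' @param cohort A [cohort_config()] (ignored when `eeg_dir` is given).
#' @param eeg_dir Optional directory with an existing cohort in the CSV +
#'   JSON container layout; must exist.
#' @param preprocess A [preprocess_config()]; when `NULL`, defaults with
#'   `target_fs` equal to the cohort sampling rate and `min_clean_s` at
#'   half the recording duration.
#' @param grid `"band"`, `"coarse"` or `"fine"` comodulogram resolution.
#' @param n_phase_bins Phase bins for the modulation index.
#' @param clinical_table Clinical data.frame; `NULL` uses the packaged
#'   26-patient table.
#' @param dti_n_per_group Subjects per group for the synthetic DTI table.
#' @param n_boot Bootstrap resamples for ROC confidence intervals.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       cohort = cohort_config(n_per_group = 8, duration_s = 60,
                                              seed = seed),
                       eeg_dir = NULL,
                       preprocess = NULL,
                       grid = c("band", "coarse", "fine"),
                       n_phase_bins = 18L,
                       clinical_table = NULL,
                       dti_n_per_group = NULL,
                       n_boot = 500L) {
  grid <- match.arg(grid)
  if (!is.null(eeg_dir) && !dir.exists(eeg_dir)) {
    stop("eeg_dir does not exist: ", eeg_dir)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort = cohort, eeg_dir = eeg_dir,
                 preprocess = preprocess, grid = grid,
                 n_phase_bins = as.integer(n_phase_bins),
                 clinical_table = clinical_table,
                 dti_n_per_group = dti_n_per_group,
                 n_boot = as.integer(n_boot)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized top-level keys: `out_dir`, `seed`, `eeg_dir`, `grid`,
#' `n_phase_bins`, `n_boot`, `dti_n_per_group` and a `cohort` mapping with
#' [cohort_config()] fields (`n_per_group`, `fs`, `duration_s`, ...).
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  cohort_args <- y$cohort %||% list()
  cohort_args$seed <- cohort_args$seed %||% seed
  cohort <- do.call(cohort_config, cohort_args)
  run_config(out_dir = y$out_dir %||% "thetapac_out", seed = seed,
             cohort = cohort, eeg_dir = y$eeg_dir,
             grid = y$grid %||% "band",
             n_phase_bins = y$n_phase_bins %||% 18L,
             dti_n_per_group = y$dti_n_per_group,
             n_boot = y$n_boot %||% 500L)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> preprocess -> band powers -> PAC -> mixed-model
#' statistics -> clinical phenotyping -> DTI asymmetry -> ROC. All
#' intermediate tables are written to `config$out_dir` as CSV/JSON along
#' with a provenance manifest (seeds, package version, file checksums) and
#' a plain-markdown report. Deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  cohort <- stage("simulate", {
    if (!is.null(config$eeg_dir)) {
      if (!dir.exists(config$eeg_dir)) {
        stop("eeg_dir does not exist: ", config$eeg_dir)
      }
      read_cohort(config$eeg_dir)
    } else {
      generate_cohort(config$cohort)
    }
  })
  note("simulate: %d recordings", length(cohort$recordings))
  write_csv_plain(cohort$manifest, file.path(out, "manifest.csv"))
  if (nrow(cohort$couplings %||% data.frame())) {
    write_csv_plain(cohort$couplings, file.path(out, "couplings.csv"))
  }

  fs0 <- cohort$recordings[[1]]$fs
  dur0 <- ncol(cohort$recordings[[1]]$data) / fs0
  pcfg <- config$preprocess %||%
    preprocess_config(target_fs = fs0, min_clean_s = dur0 / 2)
  recs <- stage("preprocess", lapply(cohort$recordings, preprocess,
                                     cfg = pcfg))
  note("preprocess: %d recordings at %g Hz", length(recs), pcfg$target_fs)

  bp <- stage("spectra", band_power_table(recs))
  write_csv_plain(bp, file.path(out, "band_power.csv"))
  note("spectra: %d band-power rows", nrow(bp))

  grid <- switch(config$grid,
                 band = band_grid(),
                 coarse = pac_grid(),
                 fine = pac_grid(fine = TRUE))
  pac <- stage("pac", pac_table(recs, grid = grid,
                                n_phase_bins = config$n_phase_bins))
  write_csv_plain(pac, file.path(out, "pac_summary.csv"))
  note("pac: %d PAC summary rows (%s grid)", nrow(pac), config$grid)

  stats_res <- stage("stats", {
    m_power <- fit_rm_lmm(bp, power ~ group * electrode * band)
    m_pac <- fit_rm_lmm(pac, mean_mi ~ group * electrode * pair)
    ph <- posthoc_contrasts(m_pac, "group", by = c("electrode", "pair"))
    outl <- iqr_outliers(pac, "mean_mi", by = c("group", "electrode", "pair"))
    list(power_model = m_power, pac_model = m_pac, pac_posthoc = ph,
         pac_outliers = outl)
  })
  cd_row <- stats_res$pac_posthoc[
    stats_res$pac_posthoc$electrode == "Cd" &
      stats_res$pac_posthoc$pair == "theta-gamma", , drop = FALSE]
  jsonlite::write_json(list(
    power_fixed_tests = stats_res$power_model$fixed_tests,
    power_r2_adj = stats_res$power_model$r2_adj,
    pac_fixed_tests = stats_res$pac_model$fixed_tests,
    pac_r2_adj = stats_res$pac_model$r2_adj,
    pac_posthoc = stats_res$pac_posthoc,
    n_pac_outliers = nrow(stats_res$pac_outliers$flags)
  ), file.path(out, "stats.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "rows")
  note("stats: group x electrode x pair model fitted; Cd theta-gamma contrast p = %.4g",
       cd_row$p[1] %||% NA_real_)

  clin <- stage("clinical", {
    tab <- config$clinical_table %||% load_paper_table1()
    desc <- cohort_descriptives(tab)
    fia <- form_impairment_analysis(tab)
    sp <- stage_and_progression(tab)
    list(table = tab, descriptives = desc, form_impairment = fia,
         staging = sp)
  })
  jsonlite::write_json(list(
    n = clin$descriptives$n,
    means = as.list(clin$descriptives$means),
    sds = as.list(clin$descriptives$sds),
    handedness = as.list(clin$descriptives$counts$handedness),
    form = as.list(clin$descriptives$counts$form),
    stage = as.list(clin$descriptives$counts$stage),
    form_impairment_chi2 = clin$form_impairment$chi2,
    form_impairment_p = clin$form_impairment$p,
    form_impairment_cramers_v = clin$form_impairment$cramers_v,
    impaired_proportion = as.list(clin$form_impairment$proportions),
    subgroups = as.list(table(clin$staging$subgroup)),
    median_progression_rate = attr(clin$staging, "median_rate")
  ), file.path(out, "clinical.json"), auto_unbox = TRUE, digits = NA)
  note("clinical: n = %d, chi2(form x impairment) = %.2f",
       clin$descriptives$n, clin$form_impairment$chi2)

  dti_res <- stage("dti", {
    n_dti <- config$dti_n_per_group %||%
      (if (is.null(config$eeg_dir)) config$cohort$n_per_group
       else length(unique(cohort$manifest$subject_id)) %/% 2L)
    dti <- generate_dti_table(n_dti, seed = child_seed(config$seed, 23L))
    asym <- asymmetry_table(dti)
    agm <- asymmetry_group_models(asym)
    list(dti = dti, asym = asym, group_models = agm)
  })
  write_csv_plain(dti_res$dti, file.path(out, "dti.csv"))
  write_csv_plain(dti_res$asym, file.path(out, "dti_asymmetry.csv"))
  jsonlite::write_json(lapply(dti_res$group_models, function(g) {
    list(group_F = g$group_test$F, group_p = g$group_test$p,
         cohens_d = g$cohens_d)
  }), file.path(out, "dti_stats.json"), auto_unbox = TRUE, digits = NA)
  note("dti: FA caudal asymmetry group contrast p = %.4g",
       dti_res$group_models$FA$group_test$p)

  roc_res <- stage("roc", {
    cd <- pac[pac$electrode == "Cd" & pac$pair == "theta-gamma", ]
    ad <- dti_res$dti[dti_res$dti$hemisphere == "dominant" &
                        dti_res$dti$level == "Brainstem", ]
    markers <- merge(cd[, c("subject_id", "group", "mean_mi")],
                     ad[, c("subject_id", "AD")], by = "subject_id")
    labels <- markers$group == "als"
    # orient scores so patients score higher (MI is reduced in ALS)
    roc_pac <- roc_curve(-markers$mean_mi, labels, n_boot = config$n_boot,
                         seed = child_seed(config$seed, 29L))
    roc_ad <- roc_curve(-markers$AD, labels, n_boot = config$n_boot,
                        seed = child_seed(config$seed, 31L))
    comb <- combine_predictors(
      data.frame(pac = -markers$mean_mi, AD = -markers$AD), labels,
      n_boot = config$n_boot, seed = child_seed(config$seed, 37L))
    list(markers = markers, pac = roc_pac, ad = roc_ad, combined = comb)
  })
  write_csv_plain(roc_res$markers, file.path(out, "markers.csv"))
  jsonlite::write_json(list(
    auc_pac = roc_res$pac$auc, auc_pac_ci = roc_res$pac$auc_ci,
    auc_ad = roc_res$ad$auc, auc_ad_ci = roc_res$ad$auc_ci,
    auc_combined = roc_res$combined$roc$auc,
    auc_combined_ci = roc_res$combined$roc$auc_ci,
    predictor_chi2 = roc_res$combined$predictor_chi2
  ), file.path(out, "roc.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "rows")
  note("roc: AUC pac = %.3f, AD = %.3f, combined = %.3f",
       roc_res$pac$auc, roc_res$ad$auc, roc_res$combined$roc$auc)

  report <- c(
    "# thetapac pipeline report", "",
    sprintf("- recordings: %d (fs %g Hz)", length(recs), pcfg$target_fs),
    sprintf("- PAC grid: %s; phase bins: %d", config$grid,
            config$n_phase_bins),
    sprintf("- group Cd theta-gamma contrast: estimate %.5g, t = %.3f, p = %.4g, d = %.3f",
            cd_row$estimate[1], cd_row$t[1], cd_row$p[1],
            cd_row$cohens_d[1]),
    sprintf("- band-power group F = %.4f (p = %.3f)",
            stats_res$power_model$fixed_tests$F[
              stats_res$power_model$fixed_tests$term == "group"],
            stats_res$power_model$fixed_tests$p[
              stats_res$power_model$fixed_tests$term == "group"]),
    sprintf("- ROC AUC: pac %.3f, AD %.3f, combined %.3f",
            roc_res$pac$auc, roc_res$ad$auc, roc_res$combined$roc$auc),
    "", "## log", "", paste("-", log_lines))
  writeLines(report, file.path(out, "report.md"))

  files <- setdiff(list.files(out), c("provenance.json"))
  manifest <- list(
    package = "thetapac",
    version = as.character(utils::packageVersion("thetapac")),
    seed = config$seed,
    grid = config$grid,
    n_phase_bins = config$n_phase_bins,
    files = as.list(tools::md5sum(file.path(out, sort(files)))))
  jsonlite::write_json(manifest, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, preprocessed = recs, band_power = bp,
                 pac = pac, stats = stats_res, clinical = clin,
                 dti = dti_res, roc = roc_res, manifest = manifest))
}
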