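#' Hemispheric asymmetry table for diffusion metrics
#'
#' Dominant-minus-nondominant difference per subject, level and metric.
#' Subjects missing one hemisphere at a level are dropped with a warning;
#' duplicated subject x hemisphere x level rows are an error.
#'
#' @param dti Long DTI data.frame as produced by [generate_dti_table()]
#'   (columns `subject_id`, `group`, `hemisphere`, `level`, `FA`, `AD`,
#'   `RD`).
#' @return data.frame with one row per subject x level x metric: columns
#'   `subject_id`, `group`, `level`, `metric`, `delta`.
#' @export
asymmetry_table <- function(dti) {
  need <- c("subject_id", "group", "hemisphere", "level", "FA", "AD", "RD")
  stopifnot(all(need %in% names(dti)))
  stopifnot(all(dti$hemisphere %in% c("dominant", "nondominant")))
  key <- paste(dti$subject_id, dti$hemisphere, dti$level)
  if (anyDuplicated(key)) {
    stop("duplicated subject x hemisphere x level rows in DTI table")
  }
  rows <- list()
  dropped <- character()
  for (sid in unique(dti$subject_id)) {
    sub <- dti[dti$subject_id == sid, , drop = FALSE]
    for (lev in unique(sub$level)) {
      cell <- sub[sub$level == lev, , drop = FALSE]
      dom <- cell[cell$hemisphere == "dominant", , drop = FALSE]
      nd <- cell[cell$hemisphere == "nondominant", , drop = FALSE]
      if (nrow(dom) != 1L || nrow(nd) != 1L) {
        dropped <- c(dropped, paste(sid, lev))
        next
      }
      for (m in c("FA", "AD", "RD")) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = dom$group, level = lev, metric = m,
          delta = dom[[m]] - nd[[m]], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(dropped)) {
    warning("dropped (missing hemisphere): ", paste(dropped, collapse = "; "))
  }
  out <- do.call(rbind, rows)
  stopifnot(all(is.finite(out$delta)))
  out
}

#' Mixed-model group analysis of diffusion metrics
#'
#' Per-metric repeated-measures linear mixed model with group, hemisphere
#' and rostro-caudal level (ordered categorical) as fixed effects including
#' the hemisphere x level interaction, random intercept per subject, plus
#' post hoc hemisphere contrasts within each level.
#'
#' @param dti Long DTI data.frame (see [asymmetry_table()] for the layout).
#' @param metrics Which metrics to model (default all three).
#' @return Named list per metric: `model` (an `rm_lmm`) and `posthoc`
#'   (hemisphere contrast per level).
#' @export
dti_group_models <- function(dti, metrics = c("FA", "AD", "RD")) {
  out <- list()
  for (m in metrics) {
    dat <- dti[, c("subject_id", "group", "hemisphere", "level", m)]
    names(dat)[5] <- "value"
    dat$level <- factor(dat$level, levels = dti_levels())
    fit <- fit_rm_lmm(dat, value ~ group * hemisphere * level,
                      subject = "subject_id", slope_factor = "hemisphere")
    ph <- posthoc_contrasts(fit, "hemisphere", by = "level")
    out[[m]] <- list(model = fit, posthoc = ph)
  }
  out
}

#' Group contrast on hemispheric asymmetry deltas
#'
#' For each metric, models the per-subject dominant-minus-nondominant
#' difference at the caudal levels (peduncle, brainstem by default) with a
#' group fixed effect, the construction used to test whether
#' handedness-related asymmetry is attenuated in patients.
#'
#' @param asym Output of [asymmetry_table()].
#' @param levels Levels included (default `c("Peduncle", "Brainstem")`).
#' @return Named list per metric: `model` (`rm_lmm`), `group_test` (row of
#'   the F table for group) and `cohens_d` (control minus ALS on per-subject
#'   mean delta).
#' @export
asymmetry_group_models <- function(asym,
                                   levels = c("Peduncle", "Brainstem")) {
  out <- list()
  for (m in unique(asym$metric)) {
    dat <- asym[asym$metric == m & asym$level %in% levels, , drop = FALSE]
    dat$level <- factor(dat$level, levels = dti_levels())
    fit <- fit_rm_lmm(dat, delta ~ group * level, subject = "subject_id")
    gt <- fit$fixed_tests[fit$fixed_tests$term == "group", , drop = FALSE]
    per_subj <- tapply(dat$delta, list(dat$subject_id), mean)
    grp <- tapply(as.character(dat$group), list(dat$subject_id),
                  function(g) g[1])
    d <- cohens_d(per_subj[grp == "control"], per_subj[grp == "als"])
    out[[m]] <- list(model = fit, group_test = gt, cohens_d = d)
  }
  out
}
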