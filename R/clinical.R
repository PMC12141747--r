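#' ECAS cognitive-impairment classification
#'
#' Applies the published ECAS cut-offs: a score strictly above the cut-off
#' (77/100 for the ALS-specific score, 105/136 for the total score) means
#' no impairment; scores at or below the cut-off are classified impaired.
#' Missing scores give an undefined (`NA`) classification, excluded from
#' contingency denominators downstream.
#'
#' @param records Clinical data.frame in the layout of
#'   [load_paper_table1()].
#' @param cutoff_specific,cutoff_total Cut-offs (defaults 77 and 105).
#' @return `records` with added logical columns `impaired_specific`,
#'   `impaired_total`.
#' @examples
#' tab <- load_paper_table1()
#' classify_impairment(tab[tab$patient_id == 21, ])[, c("impaired_specific",
#'                                                      "impaired_total")]
#' @export
classify_impairment <- function(records, cutoff_specific = 77,
                                cutoff_total = 105) {
  ok_spec <- is.na(records$ecas_specific) |
    (records$ecas_specific >= 0 & records$ecas_specific <= 100)
  ok_tot <- is.na(records$ecas_total) |
    (records$ecas_total >= 0 & records$ecas_total <= 136)
  if (!all(ok_spec) || !all(ok_tot)) {
    stop("ECAS score out of valid range")
  }
  records$impaired_specific <- !(records$ecas_specific > cutoff_specific)
  records$impaired_total <- !(records$ecas_total > cutoff_total)
  records
}

#' Cohort descriptive summary
#'
#' Means and n-1 standard deviations of the quantitative clinical scores
#' plus counts by handedness, form and disease stage.
#'
#' @param records Clinical data.frame.
#' @return List with `n`, `means`, `sds` (named, `NA` SD when n = 1) and
#'   `counts` (handedness, form, stage).
#' @export
cohort_descriptives <- function(records) {
  stopifnot(nrow(records) >= 1L)
  num_vars <- c("duration_months", "alsfrs_r", "ecas_specific", "ecas_total")
  means <- vapply(num_vars, function(v) mean(records[[v]], na.rm = TRUE), 0)
  sds <- vapply(num_vars, function(v) {
    x <- records[[v]][!is.na(records[[v]])]
    if (length(x) < 2L) NA_real_ else stats::sd(x)
  }, 0)
  stage <- ifelse(records$duration_months <= 12, "early", "late")
  list(n = nrow(records), means = means, sds = sds,
       counts = list(handedness = table(records$handedness),
                     form = table(records$form),
                     stage = table(stage)))
}

#' Pearson chi-square test of a contingency table
#'
#' Textbook Pearson chi-square without continuity correction, with
#' `df = (r - 1)(c - 1)` and Cramer's V
#' `sqrt(chi2 / (n * min(r - 1, c - 1)))`.
#'
#' @param tab Matrix (or table) of non-negative counts.
#' @return List with `chi2`, `df`, `p`, `cramers_v`, `n`, `expected`.
#' @examples
#' contingency_chi2(matrix(c(10, 0, 0, 10), 2))  # chi2 = 20, V = 1
#' @export
contingency_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), sum(tab) > 0)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has a zero marginal")
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  k <- min(nrow(tab) - 1L, ncol(tab) - 1L)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       cramers_v = sqrt(chi2 / (n * k)), n = n, expected = expected)
}

#' Disease staging and progression subgrouping
#'
#' Stage by the 12-month rule (duration <= 12 months = early, otherwise
#' late). Progression rate is the standard deltaFS construction
#' `(48 - ALSFRS-r) / duration_months` per month. Within the chosen median
#' scope (all patients, or early-stage only), patients strictly above the
#' median rate are "fast"; ties and the rest are "slow". Late-stage
#' patients are labelled `late`; early-stage are `early-fast` or
#' `early-slow`.
#'
#' @param records Clinical data.frame.
#' @param median_scope `"all"` or `"early"`: which patients define the
#'   median progression rate.
#' @return `records` with added columns `stage`, `progression_rate`,
#'   `subgroup`, plus attribute `median_rate`.
#' @examples
#' tab <- load_paper_table1()
#' out <- stage_and_progression(tab)
#' out$progression_rate[out$patient_id == 18]  # 8/3
#' @export
stage_and_progression <- function(records, median_scope = c("all", "early")) {
  median_scope <- match.arg(median_scope)
  stopifnot(all(records$duration_months > 0),
            all(!is.na(records$alsfrs_r)))
  records$stage <- ifelse(records$duration_months <= 12, "early", "late")
  records$progression_rate <- (48 - records$alsfrs_r) / records$duration_months
  scope <- if (median_scope == "early") records$stage == "early"
           else rep(TRUE, nrow(records))
  med <- stats::median(records$progression_rate[scope])
  records$subgroup <- ifelse(
    records$stage == "late", "late",
    ifelse(records$progression_rate > med, "early-fast", "early-slow"))
  attr(records, "median_rate") <- med
  records
}

#' Form-by-impairment contingency analysis
#'
#' Builds the clinical-form x ECAS-total-impairment contingency table
#' (records with missing ECAS excluded from the denominators) and tests it
#' with [contingency_chi2()]; also reports the impaired proportion per form.
#'
#' @param records Clinical data.frame.
#' @return List with `table`, `proportions` (fraction impaired per form),
#'   and the chi-square test fields.
#' @export
form_impairment_analysis <- function(records) {
  rec <- classify_impairment(records)
  rec <- rec[!is.na(rec$impaired_total), , drop = FALSE]
  tab <- table(factor(rec$form, levels = c("PUMN", "PLMN", "Classical")),
               factor(rec$impaired_total, levels = c(TRUE, FALSE),
                      labels = c("impaired", "unimpaired")))
  test <- contingency_chi2(tab)
  prop <- tab[, "impaired"] / rowSums(tab)
  c(list(table = tab, proportions = prop), test)
}
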