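#' Load the packaged clinical-features table
#'
#' Returns the 26-patient clinical table shipped with the package
#' (handedness, disease duration in months, site of onset, MRC hand scores,
#' ALSFRS-r, ECAS ALS-specific and total scores, clinical form). Patient 9
#' has missing ECAS scores, preserved as `NA`.
#'
#' @return A data.frame with columns `patient_id`, `handedness`,
#'   `duration_months`, `onset`, `mrc_right`, `mrc_left`, `alsfrs_r`,
#'   `ecas_specific`, `ecas_total`, `form`.
#' @examples
#' tab <- load_paper_table1()
#' nrow(tab)                      # 26
#' sum(tab$handedness == "left")  # 3
#' @export
load_paper_table1 <- function() {
  path <- system.file("extdata", "clinical_table1.csv", package = "thetapac",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(
    patient_id = as.integer(raw$Patient),
    handedness = tolower(raw$Handedness),
    duration_months = as.numeric(raw$Duration),
    onset = raw$Onset,
    mrc_right = as.numeric(raw$MRC_right),
    mrc_left = as.numeric(raw$MRC_left),
    alsfrs_r = as.numeric(raw$ALSFRS_r),
    ecas_specific = as.numeric(raw$ECAS_specific),
    ecas_total = as.numeric(raw$ECAS_total),
    form = raw$Form,
    stringsAsFactors = FALSE
  )
  validate_clinical(out)
  out
}

validate_clinical <- function(tab) {
  stopifnot(all(tab$handedness %in% c("right", "left")))
  stopifnot(all(tab$duration_months > 0))
  stopifnot(all(tab$mrc_right >= 0 & tab$mrc_right <= 10))
  stopifnot(all(tab$mrc_left >= 0 & tab$mrc_left <= 10))
  stopifnot(all(tab$alsfrs_r >= 0 & tab$alsfrs_r <= 48))
  ok_spec <- is.na(tab$ecas_specific) |
    (tab$ecas_specific >= 0 & tab$ecas_specific <= 100)
  ok_tot <- is.na(tab$ecas_total) |
    (tab$ecas_total >= 0 & tab$ecas_total <= 136)
  if (!all(ok_spec) || !all(ok_tot)) stop("ECAS score out of range")
  stopifnot(all(tab$form %in% c("PUMN", "PLMN", "Classical")))
  invisible(tab)
}

#' Generate a synthetic clinical table
#'
#' Draws records with the marginal structure of the packaged table:
#' log-normal disease duration, ALSFRS-r near 40, correlated ECAS scores,
#' the observed onset-site and form frequencies, and mostly right-handers.
#' Purely a testing fixture generator; respects all field ranges.
#'
#' @param n Number of records.
#' @param seed Integer seed (same seed, same table).
#' @return A data.frame in the layout of [load_paper_table1()].
#' @export
generate_clinical_table <- function(n, seed) {
  stopifnot(is_count(n), n >= 1)
  with_seed(seed, {
    duration <- pmax(1, round(exp(stats::rnorm(n, log(14), 0.8))))
    alsfrs <- pmin(48, pmax(20, round(stats::rnorm(n, 40, 4))))
    ecas_tot <- pmin(136, pmax(30, round(stats::rnorm(n, 105, 17))))
    ecas_spec <- pmin(100, pmax(20, round(ecas_tot * 0.72 +
                                            stats::rnorm(n, 0, 5))))
    onset_site <- sample(c("LL", "UL", "B"), n, replace = TRUE,
                         prob = c(12, 9, 5) / 26)
    side <- sample(c(" (left)", " (right)", ""), n, replace = TRUE,
                   prob = c(0.45, 0.45, 0.1))
    onset <- ifelse(onset_site == "B", "B",
                    paste0(onset_site, side))
    out <- data.frame(
      patient_id = seq_len(n),
      handedness = ifelse(stats::runif(n) < 23 / 26, "right", "left"),
      duration_months = duration,
      onset = onset,
      mrc_right = pmin(10, pmax(0, round(stats::rnorm(n, 9, 1.3)))),
      mrc_left = pmin(10, pmax(0, round(stats::rnorm(n, 9, 1.3)))),
      alsfrs_r = alsfrs,
      ecas_specific = ecas_spec,
      ecas_total = ecas_tot,
      form = sample(c("PUMN", "PLMN", "Classical"), n, replace = TRUE,
                    prob = c(9, 12, 5) / 26),
      stringsAsFactors = FALSE
    )
    validate_clinical(out)
    out
  })
}
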