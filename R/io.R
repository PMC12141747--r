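# EEG container: one CSV per recording (samples x channels, microvolts)
# plus a JSON sidecar carrying fs, labels, group, handedness and bad
# segments.

#' Write an EEG recording to the CSV + JSON container
#'
#' @param rec An `eeg_recording`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_eeg <- function(rec, dir) {
  stopifnot(inherits(rec, "eeg_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(rec$subject_id, ".csv"))
  json <- file.path(dir, paste0(rec$subject_id, ".json"))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  utils::write.csv(df, csv, row.names = FALSE)
  side <- list(subject_id = rec$subject_id, group = rec$group,
               handedness = rec$handedness, fs = rec$fs,
               channel_labels = rec$channel_labels,
               bad_segments = lapply(rec$bad_segments, as.numeric))
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Read an EEG recording from the CSV + JSON container
#'
#' @param dir Directory holding the container files.
#' @param subject_id Recording identifier (file stem).
#' @return An `eeg_recording`.
#' @export
read_eeg <- function(dir, subject_id) {
  csv <- file.path(dir, paste0(subject_id, ".csv"))
  json <- file.path(dir, paste0(subject_id, ".json"))
  if (!file.exists(csv) || !file.exists(json)) {
    stop("EEG container files for '", subject_id, "' not found in ", dir)
  }
  side <- jsonlite::read_json(json, simplifyVector = TRUE)
  df <- utils::read.csv(csv, check.names = FALSE)
  data <- t(as.matrix(df))
  rownames(data) <- names(df)
  bad <- side$bad_segments
  if (is.null(bad) || length(bad) == 0L) {
    bad <- list()
  } else if (is.matrix(bad)) {
    bad <- lapply(seq_len(nrow(bad)), function(i) bad[i, ])
  }
  structure(list(subject_id = side$subject_id, group = side$group,
                 handedness = side$handedness, fs = side$fs,
                 channel_labels = names(df), data = data,
                 bad_segments = bad),
            class = "eeg_recording")
}

#' Write a cohort (recordings + manifest + ground-truth couplings)
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) write_eeg(rec, dir)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$couplings, file.path(dir, "couplings.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List with `recordings`, `manifest`, `couplings`.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  recordings <- lapply(manifest$subject_id, function(sid) read_eeg(dir, sid))
  cp <- file.path(dir, "couplings.csv")
  couplings <- if (file.exists(cp)) utils::read.csv(cp, stringsAsFactors = FALSE)
               else data.frame()
  list(recordings = recordings, manifest = manifest, couplings = couplings)
}
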