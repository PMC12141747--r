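#' Corticospinal-tract sampling levels
#'
#' Rostro-caudal levels at which diffusion metrics are tabulated.
#' @return Character vector, rostral to caudal.
#' @export
dti_levels <- function() c("s.Cortex", "i.Capsule", "Peduncle", "Brainstem")

#' Default hemispheric-asymmetry offsets for synthetic DTI tables
#'
#' Dominant-minus-nondominant offsets per group, level and metric. The
#' defaults emulate handedness-related asymmetry concentrated at the caudal
#' levels (peduncle, brainstem), attenuated in the ALS group: FA higher and
#' diffusivities lower on the dominant side in controls, with smaller
#' offsets in patients.
#'
#' @return data.frame with columns `group`, `level`, `metric`, `offset`.
#' @export
default_dti_asymmetry <- function() {
  rows <- rbind(
    data.frame(group = "control", level = "Peduncle",  metric = "FA", offset = 0.03),
    data.frame(group = "control", level = "Brainstem", metric = "FA", offset = 0.04),
    data.frame(group = "als",     level = "Peduncle",  metric = "FA", offset = 0.015),
    data.frame(group = "als",     level = "Brainstem", metric = "FA", offset = 0.01),
    data.frame(group = "control", level = "Peduncle",  metric = "RD", offset = -1.5e-5),
    data.frame(group = "control", level = "Brainstem", metric = "RD", offset = -3e-5),
    data.frame(group = "als",     level = "Peduncle",  metric = "RD", offset = -1e-5),
    data.frame(group = "als",     level = "Brainstem", metric = "RD", offset = -1.5e-5),
    data.frame(group = "control", level = "Brainstem", metric = "AD", offset = -3e-5),
    data.frame(group = "als",     level = "Brainstem", metric = "AD", offset = -2e-5)
  )
  rows
}

dti_baseline <- function() {
  list(
    FA = c(s.Cortex = 0.45, i.Capsule = 0.65, Peduncle = 0.70, Brainstem = 0.60),
    AD = c(s.Cortex = 1.15e-3, i.Capsule = 1.25e-3, Peduncle = 1.35e-3,
           Brainstem = 1.20e-3),
    RD = c(s.Cortex = 5.5e-4, i.Capsule = 4.5e-4, Peduncle = 4.0e-4,
           Brainstem = 5.0e-4)
  )
}

lookup_offset <- function(spec, group, level, metric) {
  hit <- spec$group == group & spec$level == level & spec$metric == metric
  if (any(hit)) sum(spec$offset[hit]) else 0
}

#' Generate a synthetic DTI metrics table
#'
#' Long-format table of FA/AD/RD per subject, hemisphere (dominant,
#' nondominant) and corticospinal-tract level, with per-group injected
#' dominant-minus-nondominant offsets (half added to the dominant side,
#' half subtracted from the nondominant). Noise model: a subject-by-level
#' random effect shared by both hemispheres plus independent per-row
#' measurement noise, so asymmetry deltas carry only measurement noise.
#' FA values falling outside `[0, 1]` are redrawn, never clipped.
#'
#' @param n_per_group Subjects per group.
#' @param seed Integer seed.
#' @param asymmetry_spec Offsets table as in [default_dti_asymmetry()].
#' @param noise_sd Named list of measurement noise SDs per metric
#'   (defaults FA 0.015, AD 4e-5, RD 3e-5).
#' @param subject_sd Named list of subject-by-level random-effect SDs
#'   (defaults FA 0.02, AD 5e-5, RD 4e-5).
#' @return data.frame with columns `subject_id`, `group`, `hemisphere`,
#'   `level`, `FA`, `AD`, `RD`; one row per subject x hemisphere x level
#'   (`2 * n_per_group * 2 * 4` rows).
#' @export
generate_dti_table <- function(n_per_group, seed,
                               asymmetry_spec = default_dti_asymmetry(),
                               noise_sd = list(FA = 0.015, AD = 4e-5, RD = 3e-5),
                               subject_sd = list(FA = 0.02, AD = 5e-5, RD = 4e-5)) {
  stopifnot(is_count(n_per_group), n_per_group >= 1)
  base <- dti_baseline()
  levels <- dti_levels()
  with_seed(seed, {
    rows <- vector("list", 2L * n_per_group * 2L * length(levels))
    k <- 0L
    for (group in c("control", "als")) {
      for (i in seq_len(n_per_group)) {
        sid <- sprintf("%s_%02d", group, i)
        subj_re <- lapply(base, function(b)
          stats::rnorm(length(levels), 0, 1))
        for (li in seq_along(levels)) {
          lev <- levels[li]
          vals <- list(dominant = list(), nondominant = list())
          for (m in c("FA", "AD", "RD")) {
            off <- lookup_offset(asymmetry_spec, group, lev, m)
            centre <- base[[m]][[lev]] + subj_re[[m]][li] * subject_sd[[m]]
            for (hemi in c("dominant", "nondominant")) {
              mu <- centre + if (hemi == "dominant") off / 2 else -off / 2
              v <- mu + stats::rnorm(1, 0, noise_sd[[m]])
              if (m == "FA") {
                tries <- 0L
                while ((v < 0 || v > 1) && tries < 100L) {
                  v <- mu + stats::rnorm(1, 0, noise_sd[[m]])
                  tries <- tries + 1L
                }
                if (v < 0 || v > 1) stop("FA resampling failed: mean ", mu,
                                         " incompatible with [0, 1]")
              }
              vals[[hemi]][[m]] <- v
            }
          }
          for (hemi in c("dominant", "nondominant")) {
            k <- k + 1L
            rows[[k]] <- data.frame(
              subject_id = sid, group = group, hemisphere = hemi,
              level = lev, FA = vals[[hemi]]$FA, AD = vals[[hemi]]$AD,
              RD = vals[[hemi]]$RD, stringsAsFactors = FALSE)
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    if (any(out$AD < out$RD)) {
      warning("some rows have AD < RD (physically implausible tensor); ",
              "kept as generated")
    }
    out
  })
}
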