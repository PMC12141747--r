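#' IQR outlier screening per condition cell
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by
#' the linear-interpolation convention (`stats::quantile` type 7), computed
#' separately within each condition cell. Cells with fewer than 4 values
#' are skipped with a warning.
#'
#' @param data data.frame.
#' @param value Name of the numeric column screened.
#' @param by Character vector of condition columns defining the cells
#'   (empty for a single cell).
#' @return Object of class `outlier_report`: list with `fences` (one row
#'   per cell: Q1, Q3, lower, upper, n) and `flags` (the flagged rows of
#'   `data` plus their cell fences).
#' @export
iqr_outliers <- function(data, value, by = character()) {
  stopifnot(value %in% names(data), all(by %in% names(data)))
  cell_id <- if (length(by)) interaction(data[by], drop = TRUE, sep = " / ")
             else factor(rep("all", nrow(data)))
  fences <- list()
  flag_idx <- integer()
  for (cell in levels(cell_id)) {
    sel <- which(cell_id == cell & !is.na(data[[value]]))
    v <- data[[value]][sel]
    if (length(v) < 4L) {
      warning("cell '", cell, "' has fewer than 4 values; skipped")
      next
    }
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[2] + 1.5 * iqr
    fences[[length(fences) + 1L]] <- data.frame(
      cell = cell, q1 = q[1], q3 = q[2], lower = lo, upper = hi,
      n = length(v), stringsAsFactors = FALSE)
    flag_idx <- c(flag_idx, sel[v < lo | v > hi])
  }
  flags <- data[flag_idx, , drop = FALSE]
  structure(list(
    value = value, by = by,
    fences = if (length(fences)) do.call(rbind, fences) else data.frame(),
    flags = flags
  ), class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> '%s' screened in %d cell(s): %d flag(s)\n",
              x$value, nrow(x$fences), nrow(x$flags)))
  invisible(x)
}

#' Cohen's d for two samples
#'
#' `(mean(a) - mean(b)) / s_pooled` with the n-1 denominator pooled
#' standard deviation.
#'
#' @param a,b Numeric samples (each at least 2 values).
#' @return Signed effect size d.
#' @examples
#' cohens_d(c(0, 1, 2), c(2, 3, 4))  # -2
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("pooled standard deviation is zero")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors (n >= 4, finite, non-degenerate).
#' @param conf Confidence level (default 0.95).
#' @return List with `r`, `ci` (length-2), `p` (two-sided), `n`.
#' @export
pearson_corr <- function(x, y, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = length(x))
}

# Convert the character/factor columns appearing in a formula to sum-coded
# factors (required for meaningful type-III tests).
sum_code_factors <- function(data, vars) {
  for (v in vars) {
    if (!v %in% names(data)) next
    if (is.character(data[[v]]) || is.factor(data[[v]])) {
      f <- factor(data[[v]])
      stats::contrasts(f) <- stats::contr.sum(nlevels(f))
      data[[v]] <- f
    }
  }
  data
}

#' Repeated-measures linear mixed model
#'
#' REML fit of `fixed` plus a random intercept per subject and, optionally,
#' a random slope over one within-subject factor (`slope_factor`), the
#' random structure used for condition-wise repeated measures. Fixed
#' effects are tested with type-III F-tests and Satterthwaite denominator
#' degrees of freedom. A singular slope fit is automatically refitted with
#' the intercept-only random structure and flagged. When the design has a
#' single observation per subject, an ordinary linear model is fitted
#' instead (the mixed model is unidentifiable) and flagged.
#'
#' @param data Long-format data.frame.
#' @param fixed Fixed-effects formula, e.g. `mean_mi ~ group * electrode * pair`.
#' @param subject Name of the subject identifier column.
#' @param slope_factor Optional name of the within-subject factor carrying
#'   a random slope.
#' @param reml Use REML (default TRUE).
#' @return Object of class `rm_lmm`: `fit`, `fixed_tests` (term, F, df_num,
#'   df_den, p), `r2_adj`, `singular`, `refitted_intercept_only`,
#'   `used_lm`, `data`, `response`.
#' @export
fit_rm_lmm <- function(data, fixed, subject = "subject_id",
                       slope_factor = NULL, reml = TRUE) {
  stopifnot(inherits(fixed, "formula"))
  vars <- all.vars(fixed)
  resp <- vars[1]
  stopifnot(resp %in% names(data), subject %in% names(data))
  data <- data[stats::complete.cases(data[c(vars, subject)]), , drop = FALSE]
  if (stats::var(data[[resp]]) == 0) {
    stop("response '", resp, "' has zero variance; model refused")
  }
  data <- sum_code_factors(data, c(vars[-1], subject))
  data[[subject]] <- factor(data[[subject]])
  per_subject <- max(table(data[[subject]]))
  singular <- FALSE
  refitted <- FALSE
  used_lm <- FALSE
  if (per_subject <= 1L) {
    fit <- stats::lm(fixed, data = data)
    used_lm <- TRUE
    an <- car_type3_lm(fit)
    fixed_tests <- an
    fitted_v <- stats::fitted(fit)
  } else {
    make_fit <- function(rnd) {
      fml <- stats::as.formula(
        paste(deparse(fixed, width.cutoff = 500L), "+", rnd),
        env = environment())
      lmerTest::lmer(fml, data = data, REML = reml,
                     control = lme4::lmerControl(
                       check.conv.singular = lme4::.makeCC(action = "ignore",
                                                           tol = 1e-4)))
    }
    rnd <- if (is.null(slope_factor)) sprintf("(1 | %s)", subject)
           else sprintf("(1 + %s | %s)", slope_factor, subject)
    fit <- tryCatch(suppressMessages(suppressWarnings(make_fit(rnd))),
                    error = function(e) NULL)
    singular <- is.null(fit) || lme4::isSingular(fit)
    if (singular && !is.null(slope_factor)) {
      # slope structure unidentifiable or degenerate: intercept-only refit
      fit <- suppressMessages(suppressWarnings(
        make_fit(sprintf("(1 | %s)", subject))))
      refitted <- TRUE
    }
    if (is.null(fit)) stop("mixed-model fit failed")
    an <- suppressMessages(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
    fixed_tests <- data.frame(
      term = rownames(an), F = an[["F value"]], df_num = an[["NumDF"]],
      df_den = an[["DenDF"]], p = an[["Pr(>F)"]],
      stringsAsFactors = FALSE, row.names = NULL)
    fitted_v <- stats::fitted(fit)
  }
  r2 <- stats::cor(fitted_v, data[[resp]])^2
  p_fix <- length(attr(stats::terms(fixed), "term.labels"))
  n <- nrow(data)
  r2_adj <- 1 - (1 - r2) * (n - 1) / max(1, n - p_fix - 1)
  structure(list(fit = fit, fixed_tests = fixed_tests, r2_adj = r2_adj,
                 singular = singular, refitted_intercept_only = refitted,
                 used_lm = used_lm, data = data, response = resp,
                 fixed = fixed, subject = subject),
            class = "rm_lmm")
}

# Type-III F table for an lm fit (used for the one-row-per-subject case).
car_type3_lm <- function(fit) {
  an <- car::Anova(fit, type = "III")
  keep <- !rownames(an) %in% c("(Intercept)", "Residuals")
  data.frame(term = rownames(an)[keep], F = an[keep, "F value"],
             df_num = an[keep, "Df"],
             df_den = an["Residuals", "Df"],
             p = an[keep, "Pr(>F)"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.rm_lmm <- function(x, ...) {
  cat("<rm_lmm> ", deparse(x$fixed), "\n", sep = "")
  cat(sprintf("  adjusted R^2 = %.3f%s%s\n", x$r2_adj,
              if (x$refitted_intercept_only)
                "  [slope singular; refitted intercept-only]" else "",
              if (x$used_lm) "  [single obs/subject; ordinary lm]" else ""))
  print(x$fixed_tests, digits = 4)
  invisible(x)
}

#' Marginal means from a fitted repeated-measures model
#'
#' @param m An [fit_rm_lmm()] result.
#' @param specs Character vector of factor names defining the cells.
#' @return data.frame of estimated marginal means with standard errors.
#' @export
marginal_means <- function(m, specs) {
  stopifnot(inherits(m, "rm_lmm"))
  emm <- emmeans::emmeans(m$fit, specs = specs,
                          lmer.df = "satterthwaite")
  as.data.frame(emm)
}

#' Post hoc pairwise contrasts of marginal means
#'
#' Student t-tests on the estimated marginal means of `factor`, optionally
#' within cells of `by` factors, unadjusted for multiplicity by default
#' (a Holm option exists). For two-level contrasts, Cohen's d from the raw
#' cell data is attached.
#'
#' @param m An [fit_rm_lmm()] result.
#' @param factor Name of the contrasted factor.
#' @param by Optional character vector of conditioning factors.
#' @param adjust Multiplicity adjustment (default `"none"`).
#' @return data.frame of contrasts: estimate, SE, df, t, p and (where
#'   defined) `cohens_d`.
#' @export
posthoc_contrasts <- function(m, factor, by = NULL, adjust = "none") {
  stopifnot(inherits(m, "rm_lmm"))
  emm <- emmeans::emmeans(m$fit, specs = factor, by = by,
                          lmer.df = "satterthwaite")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = adjust))
  names(prs)[names(prs) == "t.ratio"] <- "t"
  names(prs)[names(prs) == "p.value"] <- "p"
  # attach raw-data Cohen's d per contrast
  d <- rep(NA_real_, nrow(prs))
  dat <- m$data
  lv <- levels(dat[[factor]])
  for (i in seq_len(nrow(prs))) {
    pair <- strsplit(as.character(prs$contrast[i]), " - ")[[1]]
    pair <- gsub("^\\(|\\)$", "", pair)
    if (length(pair) != 2L || !all(pair %in% lv)) next
    sel <- rep(TRUE, nrow(dat))
    if (!is.null(by)) {
      for (b in by) sel <- sel & dat[[b]] == prs[[b]][i]
    }
    va <- dat[[m$response]][sel & dat[[factor]] == pair[1]]
    vb <- dat[[m$response]][sel & dat[[factor]] == pair[2]]
    if (length(va) >= 2 && length(vb) >= 2) {
      d[i] <- tryCatch(cohens_d(va, vb), error = function(e) NA_real_)
    }
  }
  prs$cohens_d <- d
  prs
}

#' Local effect size f2 for a model term
#'
#' `f2 = (R2_full - R2_reduced) / (1 - R2_full)` where the reduced model
#' drops `term` (and, implicitly, nothing else) from the fixed effects;
#' R2 is the squared correlation between fitted and observed values.
#'
#' @param m An [fit_rm_lmm()] result.
#' @param term Fixed-effect term to drop (character, as in the formula).
#' @return Numeric f2.
#' @export
effect_f2 <- function(m, term) {
  stopifnot(inherits(m, "rm_lmm"))
  r2_full <- stats::cor(stats::fitted(m$fit), m$data[[m$response]])^2
  reduced <- stats::update(m$fixed, stats::as.formula(paste(". ~ . -", term)))
  m_red <- fit_rm_lmm(m$data, reduced, subject = m$subject,
                      slope_factor = NULL)
  r2_red <- stats::cor(stats::fitted(m_red$fit), m$data[[m$response]])^2
  (r2_full - r2_red) / (1 - r2_full)
}
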