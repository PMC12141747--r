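# Rank (Mann-Whitney) AUC with tie correction: probability that a random
# positive scores above a random negative, ties counting one half.
rank_auc <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve with bootstrap confidence intervals
#'
#' Threshold sweep over the observed scores (higher score = more likely
#' positive), AUC by the rank/Mann-Whitney statistic with tie correction
#' (identical to trapezoidal integration of the curve), operating point at
#' the Youden-J maximizer, and stratified bootstrap (resampling within each
#' class) percentile confidence intervals for AUC and for
#' sensitivity/specificity at the per-resample Youden point.
#'
#' @param scores Numeric predictor values (finite).
#' @param labels Logical (or 0/1, or two-level factor with the second level
#'   positive) class labels; both classes must be present.
#' @param n_boot Bootstrap resamples (default 2000; 0 skips the bootstrap).
#' @param seed Seed for the bootstrap (default 1).
#' @param conf Confidence level (default 0.95).
#' @return Object of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `auc_ci`, `threshold` (Youden), `sensitivity`, `specificity`,
#'   `sens_ci`, `spec_ci`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, n_boot = 2000L, seed = 1L,
                      conf = 0.95) {
  labels <- as_logical_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  if (!any(labels) || all(labels)) {
    stop("both classes must be present")
  }
  sweep <- roc_sweep(scores, labels)
  auc <- rank_auc(scores, labels)
  j <- sweep$tpr - sweep$fpr
  jbest <- which.max(j)
  out <- list(thresholds = sweep$thresholds, tpr = sweep$tpr,
              fpr = sweep$fpr, auc = auc,
              threshold = sweep$thresholds[jbest],
              sensitivity = sweep$tpr[jbest],
              specificity = 1 - sweep$fpr[jbest],
              n_pos = sum(labels), n_neg = sum(!labels))
  if (n_boot > 0L) {
    qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    stats_b <- with_seed(seed, {
      ipos <- which(labels); ineg <- which(!labels)
      vapply(seq_len(n_boot), function(b) {
        idx <- c(sample(ipos, length(ipos), replace = TRUE),
                 sample(ineg, length(ineg), replace = TRUE))
        s <- scores[idx]; l <- labels[idx]
        sw <- roc_sweep(s, l)
        jb <- which.max(sw$tpr - sw$fpr)
        c(rank_auc(s, l), sw$tpr[jb], 1 - sw$fpr[jb])
      }, numeric(3))
    })
    out$auc_ci <- unname(stats::quantile(stats_b[1, ], qs))
    out$sens_ci <- unname(stats::quantile(stats_b[2, ], qs))
    out$spec_ci <- unname(stats::quantile(stats_b[3, ], qs))
    out$boot_mean_auc <- mean(stats_b[1, ])
    out$boot_mean_sensitivity <- mean(stats_b[2, ])
    out$boot_mean_specificity <- mean(stats_b[3, ])
  }
  structure(out, class = "roc_result")
}

as_logical_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(labels == 1)
  }
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly two classes")
  f == levels(f)[2]
}

# Full threshold sweep: thresholds are -Inf plus the sorted unique scores;
# a point is called positive when score >= threshold.
roc_sweep <- function(scores, labels) {
  thr <- c(-Inf, sort(unique(scores)), Inf)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), 0)
  list(thresholds = thr, tpr = tpr, fpr = fpr)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f", x$auc))
  if (!is.null(x$auc_ci)) {
    cat(sprintf(" (%.3f-%.3f)", x$auc_ci[1], x$auc_ci[2]))
  }
  cat(sprintf("\n  Youden point: threshold %.4g, sens %.2f, spec %.2f  (n+ = %d, n- = %d)\n",
              x$threshold, x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' Combine predictors by logistic regression
#'
#' Standardizes the predictors, fits a logistic model of class on all of
#' them, and uses the fitted linear predictor as the combined score. Each
#' predictor's contribution is tested by a likelihood-ratio chi-square
#' (full model versus the model with that predictor deleted, df = 1),
#' with Cramer's-V-style effect size `sqrt(chi2 / n)`. Rows with missing
#' values are dropped with a warning; duplicated (collinear) predictors are
#' reported; perfect separation triggers a flagged L2-penalized fallback
#' fit.
#'
#' @param features data.frame (or matrix) of numeric predictors.
#' @param labels Class labels as in [roc_curve()].
#' @param n_boot,seed Passed to [roc_curve()] for the combined score.
#' @return List: `score` (combined linear predictor), `roc` (a
#'   `roc_result`), `predictor_chi2` (data.frame: predictor, chi2, p,
#'   cramers_v), `coefficients`, `separation` (logical flag),
#'   `rank_deficient` (character vector of aliased predictors).
#' @export
combine_predictors <- function(features, labels, n_boot = 2000L, seed = 1L) {
  features <- as.data.frame(features)
  stopifnot(ncol(features) >= 1L)
  labels <- as_logical_labels(labels)
  ok <- stats::complete.cases(features) & !is.na(labels)
  if (!all(ok)) {
    warning(sum(!ok), " row(s) with missing values dropped")
    features <- features[ok, , drop = FALSE]
    labels <- labels[ok]
  }
  X <- scale(as.matrix(features))
  dat <- data.frame(.y = labels, X)
  pred_names <- colnames(X)
  fml <- stats::as.formula(paste(".y ~", paste(pred_names, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = dat))
  aliased <- names(which(is.na(stats::coef(fit))))
  rank_deficient <- character()
  if (length(aliased)) {
    rank_deficient <- aliased
    warning("rank-deficient predictor set; aliased: ",
            paste(aliased, collapse = ", "))
  }
  p_hat <- stats::fitted(fit)
  separation <- any(p_hat > 1 - 1e-8) || any(p_hat < 1e-8) ||
    !fit$converged
  if (separation) {
    fit_pen <- penalized_logistic(X, labels, lambda = 1e-2)
    eta <- drop(cbind(1, X) %*% fit_pen)
    coefs <- fit_pen
    dev_full <- binomial_deviance(labels, stats::plogis(eta))
    chi2_tab <- lapply(pred_names, function(p) {
      Xr <- X[, setdiff(pred_names, p), drop = FALSE]
      fr <- penalized_logistic(Xr, labels, lambda = 1e-2)
      eta_r <- drop(cbind(1, Xr) %*% fr)
      chi2 <- binomial_deviance(labels, stats::plogis(eta_r)) - dev_full
      data.frame(predictor = p, chi2 = chi2,
                 p = stats::pchisq(chi2, 1, lower.tail = FALSE),
                 cramers_v = sqrt(max(0, chi2) / length(labels)))
    })
  } else {
    eta <- stats::predict(fit, type = "link")
    coefs <- stats::coef(fit)
    chi2_tab <- lapply(pred_names, function(p) {
      if (p %in% rank_deficient) {
        return(data.frame(predictor = p, chi2 = 0, p = 1, cramers_v = 0))
      }
      fml_r <- stats::as.formula(paste(". ~ . -", p))
      fit_r <- suppressWarnings(stats::update(fit, fml_r))
      chi2 <- fit_r$deviance - fit$deviance
      data.frame(predictor = p, chi2 = chi2,
                 p = stats::pchisq(chi2, 1, lower.tail = FALSE),
                 cramers_v = sqrt(max(0, chi2) / length(labels)))
    })
  }
  list(score = eta,
       roc = roc_curve(eta, labels, n_boot = n_boot, seed = seed),
       predictor_chi2 = do.call(rbind, chi2_tab),
       coefficients = coefs,
       separation = separation,
       rank_deficient = rank_deficient)
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

# Small ridge-penalized logistic fit (intercept unpenalized) by Newton
# iterations; fallback for perfectly separated data.
penalized_logistic <- function(X, y, lambda = 1e-2, max_iter = 100L) {
  Xd <- cbind(1, X)
  beta <- numeric(ncol(Xd))
  pen <- diag(c(0, rep(lambda, ncol(Xd) - 1L)), ncol(Xd))
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    grad <- crossprod(Xd, y - p) - pen %*% beta
    hess <- crossprod(Xd * w, Xd) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  drop(beta)
}
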