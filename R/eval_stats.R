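# Evaluation statistics: Mann-Whitney AUC, percentile-bootstrap CIs,
# threshold metrics with the PPV/NPV prevalence formulas, the paired
# DeLong test, and the upper-tail F-test with bootstrap-pooled variances
# used for cross-cohort AUC comparisons. All resampling is seeded and at
# the slide level (the evaluation unit).

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Fraction of (positive, negative) pairs with the positive scored higher;
#' ties count one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# One vector of B bootstrap AUCs (slide-level resampling with replacement;
# single-class resamples are redrawn).
bootstrap_aucs <- function(scores, labels, B, max_redraw = 100L) {
  n <- length(scores)
  out <- numeric(B)
  for (b in seq_len(B)) {
    for (tries in seq_len(max_redraw)) {
      idx <- sample.int(n, n, replace = TRUE)
      l <- labels[idx]
      if (any(l == 1) && any(l == 0)) break
      if (tries == max_redraw) {
        stop("degenerate bootstrap: single-class resamples after ",
             max_redraw, " redraws")
      }
    }
    out[b] <- auc(scores[idx], l)
  }
  out
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Resamples slides with replacement `B` times (redrawing resamples that
#' lose a class) and returns the percentile interval of the bootstrap AUC
#' distribution.
#'
#' @param scores,labels as in [auc()].
#' @param B bootstrap replicates (default 1000).
#' @param level confidence level.
#' @param seed RNG seed.
#' @return named vector `c(ci_low, ci_high)` with the bootstrap AUCs in
#'   attribute `"boot"`.
#' @export
bootstrap_ci <- function(scores, labels, B = 1000, level = 0.95,
                         seed = NULL) {
  with_seed(seed, {
    bs <- bootstrap_aucs(scores, labels, B)
    alpha <- (1 - level) / 2
    ci <- stats::quantile(bs, c(alpha, 1 - alpha), names = FALSE, type = 7)
    structure(c(ci_low = ci[1], ci_high = ci[2]), boot = bs)
  })
}

#' Sensitivity, specificity and prevalence at a threshold
#'
#' Predicted positive iff `score >= t` (boundary inclusive).
#'
#' @param scores,labels as in [auc()].
#' @param t decision threshold (default 0.25).
#' @return named vector sensitivity/specificity/prevalence.
#' @export
confusion_at_threshold <- function(scores, labels, t = 0.25) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  if (!any(pos) || all(pos)) stop("confusion matrix needs both classes")
  pred <- scores >= t
  c(sensitivity = mean(pred[pos]),
    specificity = mean(!pred[!pos]),
    prevalence = mean(pos))
}

#' Positive and negative predictive value from rates
#'
#' `PPV = (sens * prev) / (sens * prev + (1 - spec) * (1 - prev))` and
#' `NPV = (spec * (1 - prev)) / ((1 - sens) * prev + spec * (1 - prev))`.
#' A zero denominator (no predicted positives/negatives in expectation)
#' yields `NA` with attribute `"undefined"` naming the value.
#'
#' @param sensitivity,specificity,prevalence rates in `[0, 1]`.
#' @return named vector `c(ppv, npv)`.
#' @export
ppv_npv <- function(sensitivity, specificity, prevalence) {
  args <- c(sensitivity = sensitivity, specificity = specificity,
            prevalence = prevalence)
  if (any(args < 0 | args > 1)) {
    stop("all arguments must be rates in [0, 1]; got ",
         paste(sprintf("%s=%g", names(args), args), collapse = ", "))
  }
  undefined <- character(0)
  dp <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  dn <- (1 - sensitivity) * prevalence + specificity * (1 - prevalence)
  ppv <- if (dp > 0) sensitivity * prevalence / dp else {
    undefined <- c(undefined, "ppv"); NA_real_
  }
  npv <- if (dn > 0) specificity * (1 - prevalence) / dn else {
    undefined <- c(undefined, "npv"); NA_real_
  }
  out <- c(ppv = ppv, npv = npv)
  if (length(undefined)) attr(out, "undefined") <- undefined
  out
}

# DeLong structural components: V10 (one per positive) and V01 (one per
# negative). psi = 1, 1/2, 0 for correctly ordered / tied / inverted pairs.
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi),
       auc = mean(psi))
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares two score vectors on the same slides via DeLong's structural
#' components; the variance of the AUC difference accounts for the pairing.
#' Two-sided normal p-value. Identical score vectors (zero variance of the
#' difference) return p = 1 with attribute `"degenerate"`.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared 0/1 labels.
#' @return list with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- length(ca$v10); n <- length(ca$v01)
  if (m < 2L || n < 2L) stop("need at least two slides per class")
  var_diff <- stats::var(ca$v10 - cb$v10) / m + stats::var(ca$v01 - cb$v01) / n
  d <- ca$auc - cb$auc
  if (var_diff <= .Machine$double.eps) {
    return(structure(list(auc_a = ca$auc, auc_b = cb$auc, z = 0,
                          p_value = 1), degenerate = TRUE))
  }
  z <- d / sqrt(var_diff)
  list(auc_a = ca$auc, auc_b = cb$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

# Single-model DeLong variance (used for the variance cross-check).
delong_variance <- function(scores, labels) {
  cc <- delong_components(scores, labels)
  stats::var(cc$v10) / length(cc$v10) + stats::var(cc$v01) / length(cc$v01)
}

#' Upper-tail F-test for AUC differences across groups
#'
#' The numerator variance is the sample variance of the group AUC point
#' estimates; the denominator is the pooled variance of `B` bootstrap AUC
#' values within each group. The statistic is referred to an F
#' distribution with `g - 1` numerator and infinite denominator degrees of
#' freedom (equivalently a scaled chi-square test).
#'
#' @param groups list of `list(scores =, labels =)` per group, optionally
#'   named.
#' @param B bootstrap replicates per group.
#' @param seed RNG seed.
#' @return list of class `group_comparison`: per-group AUCs, `F_stat`,
#'   `dof_num`, `dof_den` (Inf), `p_value`.
#' @export
group_auc_ftest <- function(groups, B = 1000, seed = NULL) {
  stopifnot(length(groups) >= 2L)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_along(groups))
  for (i in seq_along(groups)) {
    l <- groups[[i]]$labels
    if (!any(l == 1) || !any(l == 0)) {
      stop("group '", nms[i], "' does not contain both classes")
    }
  }
  with_seed(seed, {
    aucs <- vapply(groups, function(g) auc(g$scores, g$labels), numeric(1))
    # each group draws its bootstrap from the same seeded stream, so the
    # statistic is exactly invariant to group ordering when seeded
    boot_var <- vapply(groups, function(g) {
      bs <- if (is.null(seed)) bootstrap_aucs(g$scores, g$labels, B)
            else with_seed(seed, bootstrap_aucs(g$scores, g$labels, B))
      stats::var(bs)
    }, numeric(1))
    g <- length(groups)
    num <- stats::var(aucs)
    den <- mean(boot_var)
    F_stat <- num / den
    p <- stats::pf(F_stat, df1 = g - 1, df2 = Inf, lower.tail = FALSE)
    structure(list(groups = stats::setNames(aucs, nms),
                   bootstrap_var = stats::setNames(boot_var, nms),
                   F_stat = F_stat, dof_num = g - 1, dof_den = Inf,
                   p_value = p),
              class = "group_comparison")
  })
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group AUC comparison (upper-tail F-test, dof ", x$dof_num,
      ", Inf):\n", sep = "")
  print(round(x$groups, 4))
  cat("F =", format(x$F_stat, digits = 4),
      " p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Full evaluation report
#'
#' AUC with percentile-bootstrap CI, sensitivity/specificity/prevalence at
#' the threshold, and PPV/NPV from the prevalence formulas.
#'
#' @param scores,labels as in [auc()].
#' @param threshold decision threshold (default 0.25).
#' @param B bootstrap replicates.
#' @param level CI level.
#' @param seed RNG seed for the bootstrap.
#' @return list of class `eval_report`.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.25,
                                 B = 1000, level = 0.95, seed = NULL) {
  a <- auc(scores, labels)
  ci <- bootstrap_ci(scores, labels, B = B, level = level, seed = seed)
  cm <- confusion_at_threshold(scores, labels, threshold)
  pn <- ppv_npv(cm[["sensitivity"]], cm[["specificity"]], cm[["prevalence"]])
  structure(list(auc = a, ci_low = unname(ci["ci_low"]),
                 ci_high = unname(ci["ci_high"]), threshold = threshold,
                 sensitivity = cm[["sensitivity"]],
                 specificity = cm[["specificity"]],
                 prevalence = cm[["prevalence"]],
                 ppv = unname(pn["ppv"]), npv = unname(pn["npv"]),
                 n_slides = length(labels), n_bootstrap = B,
                 level = level, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f), n = %d\n",
              x$auc, 100 * x$level, x$ci_low, x$ci_high, x$n_slides))
  cat(sprintf("threshold %.2f: sens %.3f spec %.3f prev %.3f  PPV %.3f NPV %.3f\n",
              x$threshold, x$sensitivity, x$specificity, x$prevalence,
              x$ppv, x$npv))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path output file.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
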