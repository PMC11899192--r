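# Cohort statistics: pooled-variance two-sample t-tests, Pearson
# correlations with two-sided t-transform p-values, muscle-fat-infiltration
# contrasts, segmentation-reproducibility coefficients of variation, and the
# measurement-noise robustness analysis. Raw per-test p-values at alpha =
# 0.05 throughout; no multiple-testing correction by default (an optional
# Holm step is available for sensitivity checks).

#' Two-sample t-test (pooled variance by default)
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param labels length-2 character vector naming the groups.
#' @param variable name of the measured quantity.
#' @param alpha significance level (default 0.05).
#' @param welch use the Welch (unequal-variance) form instead of the pooled
#'   Student form.
#' @return object of class `group_comparison`: one-row data.frame with group
#'   ns, means, sds, `t_statistic`, `df`, `p_value`, `significant`.
#' @export
two_sample_ttest <- function(a, b, labels = c("a", "b"),
                             variable = "value", alpha = 0.05,
                             welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2 || !all(is.finite(c(a, b))))
    stop("each sample needs >= 2 finite values", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                 p.value = 1)
    } else {
      stop("degenerate samples: zero variance with unequal means",
           call. = FALSE)
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = !welch)
  }
  out <- data.frame(variable = variable,
                    group1 = labels[1], group2 = labels[2],
                    n1 = length(a), n2 = length(b),
                    mean1 = mean(a), mean2 = mean(b),
                    sd1 = stats::sd(a), sd2 = stats::sd(b),
                    t_statistic = unname(tt$statistic),
                    df = unname(tt$parameter),
                    p_value = tt$p.value,
                    significant = tt$p.value < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf(
      "%s: %s (n=%d, %.3g +/- %.3g) vs %s (n=%d, %.3g +/- %.3g): t=%.3f, p=%.4g%s\n",
      x$variable[i], x$group1[i], x$n1[i], x$mean1[i], x$sd1[i],
      x$group2[i], x$n2[i], x$mean2[i], x$sd2[i],
      x$t_statistic[i], x$p_value[i],
      ifelse(x$significant[i], " *", "")))
  invisible(x)
}

#' Pearson correlation with least-squares line
#'
#' Product-moment correlation with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, plus
#' the least-squares slope and intercept for reporting.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @param x_name,y_name variable names for reporting.
#' @param alpha significance level.
#' @return object of class `correlation_result`: one-row data.frame with
#'   `n`, `r`, `p_value`, `slope`, `intercept`, `significant`.
#' @export
pearson_correlation <- function(x, y, x_name = "x", y_name = "y",
                                alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3 || !all(is.finite(c(x, y))))
    stop("need equal-length finite samples with n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm.fit(cbind(1, x), y)
  out <- data.frame(x_name = x_name, y_name = y_name,
                    n = length(x),
                    r = unname(ct$estimate),
                    p_value = ct$p.value,
                    slope = fit$coefficients[2],
                    intercept = fit$coefficients[1],
                    significant = ct$p.value < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf("%s ~ %s: n=%d, r=%.3f, p=%.4g%s (y = %.3g + %.3g x)\n",
                x$y_name[i], x$x_name[i], x$n[i], x$r[i], x$p_value[i],
                ifelse(x$significant[i], " *", ""), x$intercept[i],
                x$slope[i]))
  invisible(x)
}

#' MFI-class contrasts of the bone measurements
#'
#' For each variable (default `BT`, `BA`, `g`, `MPI`): pairwise t-tests
#' between adjacent MFI severity classes within each sex, and between the
#' sexes within each class. Contrasts with an empty or singleton cell are
#' skipped with a message.
#'
#' @param cohort data.frame with `sex`, `mfi_class` and the measured columns.
#' @param variables columns to contrast.
#' @param alpha significance level.
#' @param holm apply a Holm correction across the returned contrasts
#'   (default off: raw per-test p-values).
#' @return `group_comparison` data.frame, one row per contrast, with a
#'   `contrast` column.
#' @export
mfi_group_analysis <- function(cohort, variables = c("BT", "BA", "g", "MPI"),
                               alpha = 0.05, holm = FALSE) {
  variables <- intersect(variables, names(cohort))
  classes <- c("normal", "mild", "moderate")
  present <- classes[classes %in% unique(cohort$mfi_class)]
  out <- list()
  grab <- function(v, sex = NULL, cls = NULL) {
    sel <- rep(TRUE, nrow(cohort))
    if (!is.null(sex)) sel <- sel & cohort$sex == sex
    if (!is.null(cls)) sel <- sel & cohort$mfi_class == cls
    cohort[[v]][sel]
  }
  for (v in variables) {
    for (sex in intersect(c("F", "M"), unique(cohort$sex))) {
      if (length(present) >= 2)
        for (k in seq_len(length(present) - 1)) {
          a <- grab(v, sex, present[k]); b <- grab(v, sex, present[k + 1])
          if (length(a) < 2 || length(b) < 2) {
            message("skipping ", v, " ", sex, " ", present[k], " vs ",
                    present[k + 1], ": cell too small")
            next
          }
          cmp <- two_sample_ttest(a, b, labels = present[k + (0:1)],
                                  variable = v, alpha = alpha)
          cmp$contrast <- paste0("within-", sex)
          out[[length(out) + 1L]] <- cmp
        }
      }
    for (cls in present) {
      a <- grab(v, "F", cls); b <- grab(v, "M", cls)
      if (length(a) < 2 || length(b) < 2) {
        message("skipping ", v, " F vs M in ", cls, ": cell too small")
        next
      }
      cmp <- two_sample_ttest(a, b, labels = c("F", "M"),
                              variable = v, alpha = alpha)
      cmp$contrast <- paste0("between-sex|", cls)
      out[[length(out) + 1L]] <- cmp
    }
  }
  res <- do.call(rbind, out)
  if (isTRUE(holm) && !is.null(res)) {
    res$p_value <- stats::p.adjust(res$p_value, "holm")
    res$significant <- res$p_value < alpha
  }
  res
}

#' Coefficient of variation of repeated measurements
#'
#' Reproducibility statistic: sample standard deviation divided by the mean,
#' per measured quantity, as a fraction.
#'
#' @param repeated list of numeric vectors (or a single vector), each the
#'   repeated measurements of one quantity; >= 2 repetitions each.
#' @return named numeric vector of CV fractions.
#' @export
reproducibility_stats <- function(repeated) {
  if (!is.list(repeated)) repeated <- list(value = repeated)
  vapply(repeated, function(x) {
    if (length(x) < 2) stop("need >= 2 repetitions", call. = FALSE)
    m <- mean(x)
    if (m == 0) stop("undefined CV: mean is zero", call. = FALSE)
    stats::sd(x) / m
  }, numeric(1))
}

#' Measurement-noise robustness of a correlation
#'
#' Emulates propagating segmentation reproducibility error into the cohort
#' analysis: each execution multiplies every target value by `(1 + e)`,
#' `e ~ Normal(0, noise_fraction)`, recomputes the correlation with the
#' covariate, and the per-execution p-values are averaged and compared with
#' the noise-free baseline. The default noise budget elsewhere in the
#' package is the measured CV plus a 2% leeway.
#'
#' @param cohort data.frame holding the variables.
#' @param target_var column perturbed (e.g. `"BT"`).
#' @param covariate column correlated against (e.g. `"age"`).
#' @param noise_fraction multiplicative noise SD as a fraction (must be
#'   <= 0.5; more is implausible for segmentation error).
#' @param n_executions number of noisy executions (default 10).
#' @param alpha significance level.
#' @param seed RNG seed for reproducibility.
#' @return object of class `noise_robustness`: list with `baseline_p`,
#'   `p_values`, `mean_p`, `significance_preserved` (TRUE when every noisy
#'   execution keeps the baseline's significance classification at `alpha`).
#' @export
noise_perturbation_analysis <- function(cohort, target_var, covariate,
                                        noise_fraction, n_executions = 10L,
                                        alpha = 0.05, seed = 1L) {
  if (noise_fraction < 0) stop("noise_fraction must be >= 0", call. = FALSE)
  if (noise_fraction > 0.5)
    stop("implausible noise: noise_fraction > 0.5", call. = FALSE)
  if (n_executions < 2) stop("need n_executions >= 2", call. = FALSE)
  y <- cohort[[target_var]]; x <- cohort[[covariate]]
  if (is.null(y) || is.null(x))
    stop("missing column: ", target_var, " or ", covariate, call. = FALSE)
  baseline <- pearson_correlation(x, y, covariate, target_var, alpha)
  set.seed(seed)
  p_values <- vapply(seq_len(n_executions), function(i) {
    noisy <- y * (1 + stats::rnorm(length(y), 0, noise_fraction))
    pearson_correlation(x, noisy, covariate, target_var, alpha)$p_value
  }, numeric(1))
  structure(
    list(target_var = target_var, covariate = covariate,
         noise_fraction = noise_fraction, n_executions = n_executions,
         baseline_p = baseline$p_value,
         p_values = p_values,
         mean_p = mean(p_values),
         significance_preserved =
           all((p_values < alpha) == (baseline$p_value < alpha))),
    class = "noise_robustness")
}

#' @export
print.noise_robustness <- function(x, ...) {
  cat(sprintf(
    "<noise_robustness> %s ~ %s @ %.1f%% noise x %d runs\n  baseline p=%.4g, mean noisy p=%.4g, significance %s\n",
    x$target_var, x$covariate, 100 * x$noise_fraction, x$n_executions,
    x$baseline_p, x$mean_p,
    if (x$significance_preserved) "preserved" else "ALTERED"))
  invisible(x)
}
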