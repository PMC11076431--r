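#' Normality gate for routing parametric vs nonparametric tests
#'
#' Kolmogorov-Smirnov test of the sample against a normal distribution with
#' the sample mean and standard deviation, at level `alpha`. Degenerate
#' (constant) samples are routed non-normal.
#'
#' @param values Numeric sample, n >= 3.
#' @param alpha Significance level of the gate.
#' @return `"normal"` or `"non-normal"`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3L)
    stop("need at least 3 values to assess normality", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) return("non-normal")
  p <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), s)$p.value)
  if (p >= alpha) "normal" else "non-normal"
}

#' Compare a parameter between benign and malignant lesions
#'
#' Routes through [normality_gate()]: if both groups pass, a two-sided
#' Student's t test (pooled variance); otherwise a two-sided Mann-Whitney U
#' test. Groups too small for the gate (n < 3) are routed nonparametric.
#'
#' @param benign,malignant Parameter values per group (each n >= 2).
#' @param alpha Gate level.
#' @return An object of class `group_comparison`: group means and SDs, the
#'   test used (`"t"` or `"mann-whitney"`), the statistic and the p value.
#' @export
compare_groups <- function(benign, malignant, alpha = 0.05) {
  benign <- benign[is.finite(benign)]
  malignant <- malignant[is.finite(malignant)]
  if (length(benign) < 2L || length(malignant) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  normal <- length(benign) >= 3L && length(malignant) >= 3L &&
    normality_gate(benign, alpha) == "normal" &&
    normality_gate(malignant, alpha) == "normal"
  if (normal) {
    ht <- stats::t.test(malignant, benign, var.equal = TRUE)
    test <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(malignant, benign))
    test <- "mann-whitney"
  }
  structure(list(benign_mean = mean(benign), benign_sd = stats::sd(benign),
                 malignant_mean = mean(malignant),
                 malignant_sd = stats::sd(malignant),
                 n_benign = length(benign), n_malignant = length(malignant),
                 test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("benign %0.3g +/- %0.3g (n=%d) vs malignant %0.3g +/- %0.3g (n=%d)\n",
              x$benign_mean, x$benign_sd, x$n_benign,
              x$malignant_mean, x$malignant_sd, x$n_malignant))
  cat(sprintf("  %s test: p = %.4g\n", x$test, x$p_value))
  invisible(x)
}

# DeLong structural components. labels: logical/character; positive class
# is malignant (higher score expected in malignancy).
delong_components <- function(scores, labels) {
  pos <- as_positive(labels)
  x <- scores[pos]; y <- scores[!pos]
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L)
    stop("both classes must be present", call. = FALSE)
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp),
       m = m, n = n)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == max(labels))
  labels == "malignant"
}

#' ROC area under the curve with DeLong confidence interval
#'
#' The empirical AUC (probability a malignant score exceeds a benign one,
#' ties counted half) with the DeLong structural-components variance and a
#' normal-approximation 95% CI clipped to [0, 1]. The positive class is
#' `"malignant"` (or `TRUE`, or the larger numeric label).
#'
#' @param scores Parameter values, higher values indicating malignancy.
#' @param labels Class labels, same length as `scores`.
#' @param conf_level Confidence level for the CI.
#' @return A list: `auc`, `se`, `ci` (length 2), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  dc <- delong_components(scores, labels)
  v <- stats::var(dc$v10) / dc$m + stats::var(dc$v01) / dc$n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, dc$auc + c(-1, 1) * z * sqrt(v)))
  list(auc = dc$auc, se = sqrt(v), ci = ci, n_pos = dc$m, n_neg = dc$n)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two parameters (or two scan durations) measured on
#' the same lesions, using the covariance of their DeLong structural
#' components. Two-sided.
#'
#' @param scores_a,scores_b The two score vectors (same lesions, same order).
#' @param labels Shared class labels.
#' @return A list: `auc_a`, `auc_b`, `z`, `p_value`, `var_diff`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must have equal length", call. = FALSE)
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  vd <- stats::var(da$v10 - db$v10) / da$m +
    stats::var(da$v01 - db$v01) / da$n
  if (vd <= 0) {
    warning("zero variance of the AUC difference; reporting p = 1")
    return(list(auc_a = da$auc, auc_b = db$auc, z = 0, p_value = 1,
                var_diff = vd))
  }
  z <- (da$auc - db$auc) / sqrt(vd)
  list(auc_a = da$auc, auc_b = db$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), var_diff = vd)
}

#' Confusion-matrix metrics with exact confidence intervals
#'
#' Sensitivity, specificity, PPV, NPV and accuracy as percentages (reported
#' rounded to 2 decimals) with Clopper-Pearson exact 95% CIs on the
#' respective denominators. A metric whose denominator is empty (e.g. PPV
#' with no predicted positives) is returned as `NA`.
#'
#' @param tp,fp,tn,fn Confusion-matrix counts (malignant = positive).
#' @param conf_level Confidence level.
#' @return An object of class `confusion_metrics`: for each metric a list
#'   with `pct` (rounded to 2 decimals), `prop` (exact proportion),
#'   `num`/`den` and `ci` (percent scale); plus the counts.
#' @examples
#' m <- confusion_metrics(tp = 47, fp = 14, tn = 41, fn = 49)
#' m$sensitivity$pct  # 48.96
#' @export
confusion_metrics <- function(tp, fp, tn, fn, conf_level = 0.95) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn < 1) stop("no positives: sensitivity undefined", call. = FALSE)
  if (tn + fp < 1) stop("no negatives: specificity undefined", call. = FALSE)
  one <- function(num, den) {
    if (den == 0) return(list(pct = NA_real_, prop = NA_real_, num = num,
                              den = den, ci = c(NA_real_, NA_real_)))
    ci <- stats::binom.test(num, den, conf.level = conf_level)$conf.int
    list(pct = round(100 * num / den, 2), prop = num / den,
         num = num, den = den, ci = round(100 * as.numeric(ci), 2))
  }
  total <- tp + fp + tn + fn
  structure(list(sensitivity = one(tp, tp + fn),
                 specificity = one(tn, tn + fp),
                 ppv = one(tp, tp + fp),
                 npv = one(tn, tn + fn),
                 accuracy = one(tp + tn, total),
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  for (nm in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    m <- x[[nm]]
    cat(sprintf("  %-11s %6.2f%% (%d/%d) [%.2f, %.2f]\n", nm, m$pct,
                m$num, m$den, m$ci[1], m$ci[2]))
  }
  invisible(x)
}

#' Youden-index cutoff and diagnostic panel
#'
#' Scans every midpoint between consecutive sorted unique scores as a
#' candidate threshold (decision rule: score >= cutoff predicts malignant)
#' and picks the one maximising the Youden index J = sensitivity +
#' specificity - 1; ties are broken towards the lowest cutoff. The full
#' confusion panel and the DeLong AUC are attached. If all scores are equal
#' there is no informative cutoff and a flagged J = 0 result is returned.
#'
#' @param scores Parameter values (higher = more malignant).
#' @param labels Class labels (positive class `"malignant"`).
#' @param conf_level Confidence level for CIs.
#' @return An object of class `roc_result`: `cutoff`, `j`, `auc`, `auc_ci`,
#'   counts and a [confusion_metrics()] panel; `degenerate` flags the
#'   all-equal-scores case.
#' @export
youden_cutoff <- function(scores, labels, conf_level = 0.95) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos))
    stop("both classes must be present", call. = FALSE)
  u <- sort(unique(scores))
  roc <- roc_auc(scores, labels, conf_level)
  degenerate <- length(u) == 1L
  cand <- if (degenerate) u else (utils::head(u, -1) + utils::tail(u, -1)) / 2
  j <- vapply(cand, function(cut) {
    sens <- sum(scores >= cut & pos) / sum(pos)
    spec <- sum(scores < cut & !pos) / sum(!pos)
    sens + spec - 1
  }, numeric(1))
  best <- which.max(j)             # first maximum = lowest cutoff among ties
  cutoff <- cand[best]
  tp <- sum(scores >= cutoff & pos); fn <- sum(pos) - tp
  tn <- sum(scores < cutoff & !pos); fp <- sum(!pos) - tn
  structure(list(cutoff = cutoff, j = j[best], auc = roc$auc,
                 auc_ci = roc$ci, auc_se = roc$se,
                 metrics = confusion_metrics(tp, fp, tn, fn, conf_level),
                 degenerate = degenerate),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f [%.3f, %.3f], Youden cutoff %.4g (J = %.3f)%s\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$cutoff, x$j,
              if (x$degenerate) " [degenerate: all scores equal]" else ""))
  print(x$metrics)
  invisible(x)
}

#' Paired cross-duration comparisons with Bonferroni correction
#'
#' For one parameter in one group, tests every pair of scan durations on
#' the same lesions. If every duration's values pass the normality gate the
#' route is the paired t test; otherwise pairwise Wilcoxon signed-rank
#' tests with a Friedman omnibus reported alongside. Raw p values are
#' Bonferroni-adjusted by the number of pairs and capped at 1. Lesions with
#' any missing duration are dropped listwise.
#'
#' @param records A `kinetic_records` table from [compute_parameters()].
#' @param parameter `"ms"` or `"iauc"`.
#' @param group `"benign"` or `"malignant"`.
#' @param alpha Normality-gate level.
#' @return An object of class `paired_matrix`: the adjusted p-value matrix
#'   (durations x durations, `NA` diagonal), the raw matrix, the route,
#'   the Friedman omnibus p (nonparametric route), and the lesion count.
#' @export
paired_duration_tests <- function(records, parameter = c("ms", "iauc"),
                                  group = c("benign", "malignant"),
                                  alpha = 0.05) {
  parameter <- match.arg(parameter)
  group <- match.arg(group)
  r <- records[records$label == group, c("lesion_id", "duration_label",
                                         parameter)]
  wide <- stats::reshape(r, idvar = "lesion_id", timevar = "duration_label",
                         direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub(paste0("^", parameter, "\\."), "", colnames(mat))
  complete <- stats::complete.cases(mat)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(sprintf("%d lesion(s) dropped listwise (missing durations)",
                    n_dropped))
  mat <- mat[complete, , drop = FALSE]
  k <- ncol(mat)
  normal <- all(apply(mat, 2, function(v) normality_gate(v, alpha)) ==
                  "normal")
  raw <- matrix(NA_real_, k, k, dimnames = list(colnames(mat),
                                                colnames(mat)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d <- mat[, j] - mat[, i]
    p <- if (all(d == 0)) 1    # identical values: no evidence of change
    else if (normal) stats::t.test(d)$p.value
    else suppressWarnings(stats::wilcox.test(d)$p.value)
    raw[i, j] <- raw[j, i] <- p
  }
  n_pairs <- k * (k - 1) / 2
  adj <- raw * n_pairs
  adj[!is.na(adj) & adj > 1] <- 1
  friedman <- if (!normal)
    stats::friedman.test(mat)$p.value else NA_real_
  structure(list(parameter = parameter, group = group, adjusted = adj,
                 raw = raw, route = if (normal) "paired-t"
                 else "wilcoxon-signed-rank",
                 friedman_p = friedman, n_lesions = nrow(mat),
                 n_pairs = n_pairs, n_dropped = n_dropped),
            class = "paired_matrix")
}

#' @export
print.paired_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Paired %s comparisons, %s lesions (%s route, n = %d, %d pairs)\n",
              x$parameter, x$group, x$route, x$n_lesions, x$n_pairs))
  if (!is.na(x$friedman_p))
    cat(sprintf("  Friedman omnibus p = %.4g\n", x$friedman_p))
  disp <- ifelse(x$adjusted > 0.99, "> 0.99",
                 formatC(x$adjusted, digits = digits, format = "g"))
  disp[is.na(x$adjusted)] <- ""
  print(matrix(disp, nrow(x$adjusted), dimnames = dimnames(x$adjusted)),
        quote = FALSE)
  invisible(x)
}

#' Intraclass correlation for two raters or sessions
#'
#' ICC(A,1): two-way random effects, single measures, absolute agreement,
#' from the two-way ANOVA mean squares, with the F-based confidence
#' interval of McGraw and Wong. Suitable for inter-observer (two raters) or
#' intra-observer (two sessions) agreement on the same lesions.
#'
#' @param ratings_a,ratings_b Paired measurements on the same lesions,
#'   n >= 5.
#' @param conf_level Confidence level.
#' @return An object of class `icc_result`: `icc`, `ci`, mean squares and
#'   the design descriptor. ICC is `NA` (flagged) when the between-lesion
#'   variance is zero.
#' @export
icc_agreement <- function(ratings_a, ratings_b, conf_level = 0.95) {
  stopifnot(length(ratings_a) == length(ratings_b))
  ok <- is.finite(ratings_a) & is.finite(ratings_b)
  a <- ratings_a[ok]; b <- ratings_b[ok]
  n <- length(a)
  if (n < 5L) stop("need at least 5 paired ratings", call. = FALSE)
  k <- 2
  x <- cbind(a, b)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (msr <= 0 || denom <= 0) {
    warning("zero between-lesion variance; ICC undefined")
    return(structure(list(icc = NA_real_, ci = c(NA_real_, NA_real_),
                          msr = msr, msc = msc, mse = mse, n = n,
                          design = "two-way random, single measures, absolute agreement"),
                     class = "icc_result"))
  }
  icc <- (msr - mse) / denom
  alpha <- 1 - conf_level
  aa <- k * icc / (n * (1 - icc))
  bb <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (aa * msc + bb * mse)^2 /
    ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  if (!is.finite(v) || v <= 0) {
    # perfect agreement (zero residual and column variance): degenerate CI
    lower <- upper <- icc
  } else {
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  }
  structure(list(icc = icc, ci = c(max(-1, lower), min(1, upper)),
                 msr = msr, msc = msc, mse = mse, n = n,
                 design = "two-way random, single measures, absolute agreement"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f [%.3f, %.3f] (n = %d; %s)\n",
              x$icc, x$ci[1], x$ci[2], x$n, x$design))
  invisible(x)
}
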