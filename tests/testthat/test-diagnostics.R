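test_that("normality gate routes normal and log-normal samples correctly", {
  normal_hits <- vapply(1:100, function(s) {
    set.seed(s); normality_gate(rnorm(500)) == "normal"
  }, logical(1))
  expect_gte(mean(normal_hits), 0.90)
  lognormal_hits <- vapply(1:100, function(s) {
    set.seed(s); normality_gate(rlnorm(500)) == "non-normal"
  }, logical(1))
  expect_gte(mean(lognormal_hits), 0.99)
  expect_equal(normality_gate(rep(1, 10)), "non-normal")
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("group comparison handles identical groups and matches exact Mann-Whitney", {
  g <- c(1, 2, 3, 4, 5)
  res <- compare_groups(g, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$test, "t")
  # the Mann-Whitney route equals exact enumeration over all 20 splits
  oracle <- mw_exact_enumeration(c(1, 2, 3), c(4, 5, 6))
  mw <- suppressWarnings(wilcox.test(c(4, 5, 6), c(1, 2, 3)))$p.value
  expect_equal(mw, oracle)
  expect_error(compare_groups(1, c(2, 3)), "at least 2")
})

test_that("group comparison holds its type-I error under the null", {
  reject <- vapply(1:500, function(s) {
    set.seed(s)
    compare_groups(rnorm(20), rnorm(25))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("AUC equals the pair-counting oracle on exhaustive small instances", {
  set.seed(31)
  for (rep in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    scores <- sample(1:5, n1 + n2, replace = TRUE)  # forces ties
    labels <- rep(c("benign", "malignant"), c(n1, n2))
    expect_equal(roc_auc(scores, labels)$auc, auc_pair_count(scores, labels))
  }
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       rep(c("benign", "malignant"), each = 3))$auc, 1)
  expect_error(roc_auc(1:4, rep("malignant", 4)), "both classes")
})

test_that("AUC and DeLong CI agree with the independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- c(rnorm(25), rnorm(35, 1))
  labels <- rep(c("benign", "malignant"), c(25, 35))
  mine <- roc_auc(scores, labels)
  ref <- pROC::roc(labels, scores, levels = c("benign", "malignant"),
                   direction = "<", quiet = TRUE)
  expect_equal(mine$auc, as.numeric(ref$auc))
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$ci, ref_ci[c(1, 3)], tolerance = 1e-8)
})

test_that("null AUC centres at one half", {
  set.seed(17)
  aucs <- vapply(1:1000, function(i) {
    roc_auc(rnorm(30), rep(c("benign", "malignant"), each = 15))$auc
  }, numeric(1))
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se)
})

test_that("empirical AUC recovers the binormal closed form at n = (55, 96)", {
  mu0 <- 0; mu1 <- 1; s0 <- 1; s1 <- 1.5
  theory <- pnorm((mu1 - mu0) / sqrt(s0^2 + s1^2))
  set.seed(23)
  aucs <- vapply(1:400, function(i) {
    scores <- c(rnorm(55, mu0, s0), rnorm(96, mu1, s1))
    roc_auc(scores, rep(c("benign", "malignant"), c(55, 96)))$auc
  }, numeric(1))
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - theory), 3 * se)
})

test_that("paired DeLong test is degenerate-safe, calibrated, and matches pROC", {
  scores <- c(rnorm(20), rnorm(20, 1))
  labels <- rep(c("benign", "malignant"), each = 20)
  expect_warning(res <- delong_paired_test(scores, scores, labels),
                 "zero variance")
  expect_equal(res$p_value, 1)

  reject <- vapply(1:500, function(s) {
    set.seed(10000 + s)
    labs <- rep(c("benign", "malignant"), c(25, 30))
    delong_paired_test(rnorm(55), rnorm(55), labs)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)

  skip_if_not_installed("pROC")
  set.seed(77)
  labs <- rep(c("benign", "malignant"), c(28, 32))
  a <- rnorm(60) + (labs == "malignant") * 0.8
  b <- 0.6 * a + rnorm(60)
  mine <- delong_paired_test(a, b, labs)
  ra <- pROC::roc(labs, a, levels = c("benign", "malignant"),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(labs, b, levels = c("benign", "malignant"),
                  direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("DeLong variance of the AUC difference agrees with a paired bootstrap", {
  set.seed(99)
  labs <- rep(c("benign", "malignant"), c(28, 32))
  a <- rnorm(60) + (labs == "malignant") * 1
  b <- 0.7 * a + 0.5 * rnorm(60)
  analytic <- delong_paired_test(a, b, labs)$var_diff
  boots <- vapply(1:2000, function(i) {
    idx <- c(sample(which(labs == "benign"), replace = TRUE),
             sample(which(labs == "malignant"), replace = TRUE))
    da <- delong_components(a[idx], labs[idx])
    db <- delong_components(b[idx], labs[idx])
    da$auc - db$auc
  }, numeric(1))
  expect_lt(abs(var(boots) - analytic) / analytic, 0.15)
})

test_that("Youden cutoff equals the exhaustive threshold scan", {
  res <- youden_cutoff(c(1, 2, 3, 4), c("benign", "benign", "malignant",
                                        "malignant"))
  expect_equal(res$cutoff, 2.5)
  expect_equal(res$j, 1)
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 2, by = 0.25), n, replace = TRUE)
    labels <- c("benign", "malignant",
                sample(c("benign", "malignant"), n - 2, replace = TRUE))
    mine <- youden_cutoff(scores, labels)
    oracle <- youden_exhaustive(scores, labels)
    expect_equal(mine$j, oracle$j)
  }
  # ties at the optimum resolve to the lowest candidate cutoff
  sc <- c(1, 2, 3, 4, 5, 6)
  lb <- c("benign", "benign", "benign", "malignant", "malignant", "malignant")
  expect_equal(youden_cutoff(sc, lb)$cutoff, 3.5)
  # all-equal scores: flagged degenerate with J = 0
  deg <- youden_cutoff(rep(2, 6), lb)
  expect_true(deg$degenerate)
  expect_equal(deg$j, 0)
})

test_that("confusion metrics are self-consistent and exactly recomputable", {
  m <- confusion_metrics(tp = 1, fp = 0, tn = 1, fn = 0)
  for (nm in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
    expect_equal(m[[nm]]$pct, 100)
  m2 <- confusion_metrics(tp = 10, fp = 40, tn = 5, fn = 2)
  for (nm in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    expect_equal(m2[[nm]]$pct, round(100 * m2[[nm]]$num / m2[[nm]]$den, 2))
    ci <- binom.test(m2[[nm]]$num, m2[[nm]]$den)$conf.int
    expect_equal(m2[[nm]]$ci, round(100 * as.numeric(ci), 2))
  }
  # empty predicted-positive margin: PPV reported missing
  m3 <- confusion_metrics(tp = 0, fp = 0, tn = 5, fn = 3)
  expect_true(is.na(m3$ppv$pct))
})

test_that("paired duration tests route, adjust and cap correctly", {
  acq <- acquisition_params()
  sets <- build_dynamic_sets(acq)
  study <- simulate_cohort(cohort_spec(n_benign = 12, n_malignant = 15,
                                       seed = 8), acq)
  rec <- compute_parameters(study, sets)
  pm <- paired_duration_tests(rec, "iauc", "malignant")
  expect_true(isSymmetric(pm$adjusted))
  expect_true(all(is.na(diag(pm$adjusted))))
  expect_true(all(pm$adjusted >= pm$raw - 1e-15, na.rm = TRUE))
  expect_true(all(pm$adjusted <= 1, na.rm = TRUE))
  # identical iAUC once the 60 s window is covered: adjusted p = 1
  expect_equal(pm$adjusted["SD_67.5s", "SD_135s"], 1)
  expect_equal(pm$n_pairs, 28)
})

test_that("paired t route reproduces the textbook hand computation", {
  # 5 lesions at two durations; hand formula: t = dbar / (sd / sqrt(n))
  a <- c(0.42, 0.51, 0.38, 0.66, 0.47)
  b <- c(0.49, 0.58, 0.41, 0.70, 0.55)
  d <- b - a
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(t.test(b, a, paired = TRUE)$p.value, p_hand)
  rec <- data.frame(
    lesion_id = rep(sprintf("L%d", 1:5), each = 2),
    label = "malignant",
    duration_label = rep(c("SD_a", "SD_b"), 5),
    ms = as.numeric(rbind(a, b)), iauc = 0)
  pm <- paired_duration_tests(rec, "ms", "malignant")
  expect_equal(pm$raw["SD_a", "SD_b"], p_hand)
  expect_equal(pm$adjusted["SD_a", "SD_b"], min(1, p_hand * 1))
})

test_that("family-wise error of the paired procedure stays controlled under the null", {
  k <- 4
  fwer <- vapply(1:500, function(s) {
    set.seed(20000 + s)
    base <- rnorm(15)
    rec <- do.call(rbind, lapply(1:k, function(j)
      data.frame(lesion_id = sprintf("L%d", 1:15), label = "benign",
                 duration_label = sprintf("SD_%d", j),
                 ms = base + rnorm(15), iauc = 0)))
    pm <- paired_duration_tests(rec, "ms", "benign")
    any(pm$adjusted < 0.05, na.rm = TRUE)
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lte(mean(fwer), 0.05 + 2 * se)
})

test_that("ICC(A,1) matches the ANOVA decomposition and its definitional properties", {
  a <- c(9, 6, 8, 7, 10, 6)
  b <- c(2, 1, 4, 1, 5, 2)
  res <- icc_agreement(a, b)
  # oracle: mean squares from aov() on the long two-way layout
  long <- data.frame(y = c(a, b),
                     subj = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  ms <- anova(aov(y ~ subj + rater, data = long))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 6)
  expect_equal(res$icc, icc_oracle)
  # identity: perfect agreement
  expect_equal(icc_agreement(a, a)$icc, 1)
  # constant shift: absolute agreement < consistency
  set.seed(3)
  x <- rnorm(60)
  shift <- icc_agreement(x, x + 1)$icc
  consistency <- cor(x, x + 1)   # consistency ICC -> correlation here
  expect_lt(shift, consistency)
  expect_error(icc_agreement(1:3, 1:3), "at least 5")
  expect_warning(icc_agreement(rep(1, 6), rep(1, 6)), "undefined")
})
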