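test_that("contingency tables count the four cells and conserve totals", {
  fx <- table3_fixture()
  tab <- contingency_table(fx$scores, fx$labels, 6)
  expect_equal(unclass(tab)[c("tp", "fn", "fp", "tn")],
               list(tp = 42L, fn = 7L, fp = 7L, tn = 95L))
  # all-positive labels at cut 0
  t2 <- contingency_table(c(1, 2, 3), referral_labels(c(1, 1, 1)), 0)
  expect_equal(t2$fn + t2$fp + t2$tn, 0L)
  # cut above the maximum score
  t3 <- contingency_table(fx$scores, fx$labels, 99)
  expect_equal(t3$tp + t3$fp, 0L)
  expect_error(contingency_table(numeric(0), referral_labels(logical(0)), 1),
               "no persons")
})

test_that("diagnostic metrics reproduce the cut-6 published row", {
  tab <- structure(list(tp = 42L, fn = 7L, fp = 7L, tn = 95L),
                   class = "confusion_table")
  m <- diagnostic_metrics(tab)
  expect_equal(round(m$odds_ratio, 2), 81.43)
  expect_equal(round(m$sensitivity, 2), 85.71)
  expect_equal(round(m$specificity, 2), 93.14)
  expect_equal(round(m$ppv, 1), 85.7)
  expect_equal(round(m$npv, 1), 93.1)
  expect_equal(round(m$pct_correct, 1), 90.7)
})

test_that("zero-cell odds ratios follow the configured policy", {
  tab <- structure(list(tp = 1L, fn = 48L, fp = 0L, tn = 102L),
                   class = "confusion_table")
  m <- diagnostic_metrics(tab, "undefined")
  expect_true(is.na(m$odds_ratio))
  expect_equal(m$specificity, 100)
  mh <- diagnostic_metrics(tab, "haldane")
  expect_equal(mh$odds_ratio, (1.5 * 102.5) / (48.5 * 0.5),
               tolerance = 1e-12)
  # perfect classifier
  perfect <- structure(list(tp = 10L, fn = 0L, fp = 0L, tn = 10L),
                       class = "confusion_table")
  mp <- diagnostic_metrics(perfect)
  expect_equal(c(mp$sensitivity, mp$specificity, mp$ppv, mp$npv),
               rep(100, 4))
  expect_true(is.na(mp$odds_ratio))
})

test_that("the rank AUC equals the brute-force all-pairs concordance", {
  set.seed(19)
  for (r in 1:5) {
    scores <- sample(0:10, 20, replace = TRUE)
    y <- as.logical(rbinom(20, 1, 0.5))
    if (!any(y) || all(y)) next
    got <- roc_auc(scores, y)$auc
    pos <- scores[y]; neg <- scores[!y]
    pairs <- outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(got, mean(pairs), tolerance = 1e-12)
    # ties-symmetric complement identity
    expect_equal(roc_auc(-scores, y)$auc, 1 - got, tolerance = 1e-12)
  }
})

test_that("the rank AUC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(20)
  scores <- rnorm(80)
  y <- rbinom(80, 1, plogis(scores))
  if (length(unique(y)) == 2) {
    ref <- suppressMessages(as.numeric(pROC::auc(y, scores)))
    expect_equal(roc_auc(scores, y)$auc, ref, tolerance = 1e-10)
  }
})

test_that("AUC is ~0.5 for labels independent of scores, errors one-class", {
  set.seed(21)
  scores <- rnorm(4000)
  y <- rbinom(4000, 1, 0.4)
  expect_lt(abs(roc_auc(scores, y)$auc - 0.5), 0.03)
  expect_error(roc_auc(scores, rep(TRUE, 4000)), "both classes")
})

test_that("cutpoint sweep matches single calls and is monotone in the cut", {
  fx <- table3_fixture()
  sweep <- cutpoint_sweep(fx$scores, fx$labels, c(21, 9, 6, 4, 1))
  single <- cutpoint_sweep(fx$scores, fx$labels, 6)
  expect_equal(sweep[sweep$cut == 6, ], single, ignore_attr = TRUE)
  ordered <- sweep[order(sweep$cut), ]
  expect_true(all(diff(ordered$sensitivity) <= 1e-12))
  expect_true(all(diff(ordered$specificity) >= -1e-12))
  # N conserved across cuts
  expect_true(all(rowSums(sweep[, c("tp", "fn", "fp", "tn")]) == 151))
  # per-cut c equals (Se + Sp)/2 exactly
  expect_equal(sweep$c_statistic,
               (sweep$sensitivity + sweep$specificity) / 200,
               tolerance = 1e-12)
})

test_that("logistic slope equals the log cross-product odds ratio", {
  fx <- table3_fixture()
  x <- as.integer(classify_referral(fx$scores, 6))
  lg <- fit_logistic(x, fx$labels)
  expect_true(lg$converged)
  tab <- contingency_table(fx$scores, fx$labels, 6)
  or <- diagnostic_metrics(tab)$odds_ratio
  expect_equal(exp(lg$slope), or, tolerance = 1e-6)
  expect_equal(round(exp(lg$slope), 2), 81.43)
})

test_that("separation is flagged where the odds ratio is undefined", {
  fx <- table3_fixture()
  x21 <- as.integer(classify_referral(fx$scores, 21))  # fp = 0
  lg <- fit_logistic(x21, fx$labels)
  expect_true(lg$separation)
  expect_false(lg$converged)
  expect_error(fit_logistic(c(0, 1, 0), referral_labels(c(1, 1, 1))),
               "both classes")
})

test_that("Hosmer-Lemeshow follows its contracts on small cases", {
  set.seed(22)
  x <- rnorm(200); p <- plogis(-0.2 + x); y <- rbinom(200, 1, p)
  fit <- stats::glm(y ~ x, family = stats::binomial())
  hl <- hosmer_lemeshow(stats::fitted(fit), y, groups = 10)
  expect_equal(hl$df, 8L)          # 10 groups, no merges
  expect_equal(hl$groups_used, 10L)
  expect_true(hl$p_value >= 0 && hl$p_value <= 1)

  # two-group hand computation
  p2 <- c(0.2, 0.2, 0.4, 0.8, 0.8, 0.6)
  y2 <- c(0, 1, 0, 1, 1, 0)
  hl2 <- suppressWarnings(hosmer_lemeshow(p2, y2, groups = 3))
  o <- order(p2); ps <- p2[o]; ys <- y2[o]
  grp <- rep(1:3, each = 2)
  O <- tapply(ys, grp, sum); n_g <- tabulate(grp); pb <- tapply(ps, grp, mean)
  chi2 <- sum((O - n_g * pb)^2 / (n_g * pb * (1 - pb)))
  expect_equal(hl2$chi2, chi2, tolerance = 1e-12)
  expect_equal(hl2$p_value, stats::pchisq(chi2, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})
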