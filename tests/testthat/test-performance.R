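test_that("confusion matrix counts the four cells and rejects bad input", {
  cm <- confusionMatrix(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(cmCounts(cm), c(tp = 2L, fn = 0L, fp = 0L, tn = 2L))
  cm2 <- confusionMatrix(c(1, 1, 1, 1), c(1, 0, 1, 0))
  expect_equal(cmCounts(cm2), c(tp = 2L, fn = 0L, fp = 2L, tn = 0L))
  expect_error(confusionMatrix(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(confusionMatrix(numeric(0), numeric(0)), "empty")
  ## recount: cells always sum to n
  set.seed(14)
  p <- rbinom(865, 1, 0.5); t <- rbinom(865, 1, 0.5)
  expect_equal(sum(cmCounts(confusionMatrix(p, t))), 865L)
})

test_that("diagnostic metrics reproduce the published overall SLERPI row", {
  cm <- new("ConfusionMatrix", tp = 415L, fn = 20L, fp = 31L, tn = 399L)
  dm <- diagnosticMetrics(cm)
  expect_equal(roundHalfAway(dm$point_pct, 1), c(95.4, 92.8, 94.1))
  expect_equal(roundHalfAway(dm$ci_low_pct[dm$metric == "sensitivity"], 1), 93.0)
  expect_equal(roundHalfAway(dm$ci_high_pct[dm$metric == "sensitivity"], 1), 97.2)
  ## nephritis subgroup row: 120/125 sensitive against the same controls
  cmN <- new("ConfusionMatrix", tp = 120L, fn = 5L, fp = 31L, tn = 399L)
  dmN <- diagnosticMetrics(cmN)
  expect_equal(roundHalfAway(dmN$point_pct[1], 1), 96.0)
  expect_equal(roundHalfAway(dmN$point_pct[3], 1), 93.5)
  ## perfect classifier
  dmP <- diagnosticMetrics(new("ConfusionMatrix", tp = 7L, fn = 0L,
                               fp = 0L, tn = 9L))
  expect_equal(dmP$point_pct, c(100, 100, 100))
  expect_error(diagnosticMetrics(new("ConfusionMatrix", tp = 0L, fn = 0L,
                                     fp = 1L, tn = 1L)), "sensitivity")
})

test_that("accuracy identity holds for arbitrary confusion matrices", {
  set.seed(15)
  for (i in 1:50) {
    cnt <- as.integer(rmultinom(1, sample(20:500, 1) + 4, rep(0.25, 4)) + 1L)
    cm <- new("ConfusionMatrix", tp = cnt[1], fn = cnt[2], fp = cnt[3],
              tn = cnt[4])
    dm <- diagnosticMetrics(cm)
    P <- cnt[1] + cnt[2]; N <- cnt[3] + cnt[4]
    sens <- dm$point_pct[1]; spec <- dm$point_pct[2]
    expect_equal(dm$point_pct[3], (sens * P + spec * N) / (P + N))
  }
})

test_that("Clopper-Pearson interval: boundaries, printed CI, cross-check", {
  expect_equal(clopperPearson(0, 10)[["low"]], 0)
  expect_equal(clopperPearson(10, 10)[["high"]], 1)
  expect_equal(unname(round(clopperPearson(415, 435), 3)), c(0.930, 0.972))
  expect_error(clopperPearson(5, 10, conf_level = 1.2), "conf_level")
  ## cross-check against the exact binomial test over assorted (x, n)
  for (x in c(0, 1, 7, 50, 415)) {
    n <- max(10, x)
    bt <- stats::binom.test(x, n)$conf.int
    expect_equal(unname(clopperPearson(x, n)), as.numeric(bt),
                 tolerance = 1e-10)
  }
})

test_that("ROC handles separation, total ties, and matches pROC", {
  expect_equal(auc(rocCurve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))), 1)
  expect_equal(auc(rocCurve(rep(2, 10), rep(0:1, 5))), 0.5)
  expect_error(rocCurve(1:4, c(1, 1, 1, 1)), "both classes")
  ## 20-point toy set against the O(n^2) pair-count oracle
  set.seed(16)
  sc <- sample(1:8, 20, replace = TRUE)
  tr <- rbinom(20, 1, 0.5); tr[1] <- 1; tr[2] <- 0
  expect_equal(auc(rocCurve(sc, tr)), oracleAUC(sc, tr))
  skip_if_not_installed("pROC")
  pauc <- as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE,
                                         direction = "<")))
  expect_equal(auc(rocCurve(sc, tr)), pauc, tolerance = 1e-12)
})

test_that("AUC equals the scaled Mann-Whitney statistic with midrank ties", {
  ## property over many random small instances, heavy ties included
  set.seed(17)
  for (i in 1:300) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    sc <- c(sample(1:5, n1, replace = TRUE) + rnorm(n1, 0, 0.2) * rbinom(n1, 1, 0.5),
            sample(1:5, n2, replace = TRUE))
    tr <- c(rep(1, n1), rep(0, n2))
    a <- auc(rocCurve(sc, tr))
    u <- suppressWarnings(stats::wilcox.test(sc[tr == 1], sc[tr == 0]))$statistic
    expect_equal(a, unname(u) / (n1 * n2), tolerance = 1e-12)
    expect_equal(a, oracleAUC(sc, tr), tolerance = 1e-12)
  }
})

test_that("stratified performance: filters cases, keeps all controls", {
  coh <- generateCohort(defaultCohortSpec(), seed = 19)
  res <- applyCriteria(coh, bundledCriteria("SLERPI"))
  truth <- as.integer(cohortGroups(coh) == "case")
  cd <- as.data.frame(SummarizedExperiment::colData(coh))
  ## identity filter equals the unstratified metrics
  all1 <- stratifiedPerformance(coh, res, rep(TRUE, ncol(coh)))
  all2 <- diagnosticMetrics(confusionMatrix(res$classified, truth))
  expect_equal(all1, all2)
  ## nephritis stratum: sensitivity denominator is the flagged-case count
  neph <- stratifiedPerformance(coh, res, function(d) d$nephritis == 1)
  nNeph <- sum(cd$nephritis == 1 & cd$group == "case")
  expect_equal(neph$denominator[neph$metric == "sensitivity"], nNeph)
  expect_equal(neph$denominator[neph$metric == "specificity"], 430L)
  ## polyA-negative stratum mirrors the published subgroup construction
  noPolyA <- stratifiedPerformance(coh, res, cd$polyA == 0)
  expect_equal(noPolyA$denominator[1],
               sum(cd$polyA == 0 & cd$group == "case"))
  ## specificity invariance: any case filter leaves specificity unchanged
  for (f in list(cd$nephritis == 1, cd$hematological == 1, cd$polyA == 0)) {
    s <- stratifiedPerformance(coh, res, f)
    expect_equal(s[s$metric == "specificity", ],
                 all2[all2$metric == "specificity", ])
  }
  expect_error(stratifiedPerformance(coh, res, rep(FALSE, ncol(coh))),
               "no cases")
})

test_that("count reconstruction inverts printed one-decimal rates", {
  expect_equal(reconstructCount(95.4, 435), 415L)
  expect_equal(reconstructCount(92.8, 430), 399L)
  expect_error(reconstructCount(10.0, 10000), "ambiguous")
  expect_error(reconstructCount(99.9, 3), "inconsistent")
  ## round trip: reconstruct(rate(k)) = k whenever rounding is injective
  set.seed(20)
  for (i in 1:50) {
    d <- sample(50:900, 1)
    k <- sample(0:d, 1)
    rate <- roundHalfAway(100 * k / d, 1)
    got <- tryCatch(reconstructCount(rate, d), error = function(e) NA_integer_)
    if (!is.na(got)) expect_equal(got, k)
  }
})

test_that("exact intervals cover the truth at least at nominal rate", {
  ## coverage at n = 435, p = 0.95, many replicates (exact CIs conservative)
  set.seed(22)
  n <- 435L; p <- 0.95; reps <- 2000L
  x <- rbinom(reps, n, p)
  cover <- vapply(x, function(xi) {
    ci <- clopperPearson(xi, n)
    ci[["low"]] <= p && p <= ci[["high"]]
  }, logical(1))
  expect_gte(mean(cover), 0.95 - 2 * sqrt(0.05 * 0.95 / reps))
})
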