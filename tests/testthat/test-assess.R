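test_that("classification metrics follow the printed equations", {
  # 106 of 110 reference kinases recovered
  expect_equal(metricsVector(classMetrics(ConfusionCounts(106, 0, 0, 4)),
                             digits = 2)[["sn"]], 0.96)
  # 1091 of 1535 reference RBPs recovered
  expect_equal(metricsVector(classMetrics(ConfusionCounts(1091, 0, 0, 444)),
                             digits = 2)[["sn"]], 0.71)
  # perfect classifier
  mv <- metricsVector(classMetrics(ConfusionCounts(7, 0, 9, 0)))
  expect_equal(unname(mv), c(1, 1, 1, 1, 1))
  # direct MCC evaluation
  expect_equal(metricsVector(classMetrics(ConfusionCounts(5, 1, 4, 2)))[["mcc"]],
               18 / sqrt(1260))
  # F combines SN and SP (not precision/recall)
  m <- classMetrics(ConfusionCounts(8, 4, 6, 2))
  mv <- metricsVector(m)
  expect_equal(mv[["fmeasure"]],
               2 * mv[["sn"]] * mv[["sp"]] / (mv[["sn"]] + mv[["sp"]]))
  # zero denominators define the metric as 0
  z <- metricsVector(classMetrics(ConfusionCounts(0, 0, 0, 0)))
  expect_equal(unname(z), c(0, 0, 0, 0, 0))
})

test_that("metrics are invariant to scaling all four counts", {
  set.seed(21)
  for (i in 1:10) {
    c0 <- sample(0:40, 4)
    k <- sample(2:9, 1)
    m1 <- metricsVector(classMetrics(ConfusionCounts(c0[1], c0[2], c0[3], c0[4])))
    m2 <- metricsVector(classMetrics(ConfusionCounts(k * c0[1], k * c0[2],
                                                     k * c0[3], k * c0[4])))
    expect_equal(m1, m2)
  }
})

test_that("ROC curves match the rank-sum oracle and an external reference", {
  # perfectly separating scores
  r <- rocCurve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(aucOf(r), 1)
  expect_equal(r@points$fpr[1], 0)
  expect_equal(utils::tail(rocPoints(r)$tpr, 1), 1)

  # 4-point toy set with an inversion
  sc <- c(0.9, 0.4, 0.6, 0.1)
  lb <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(aucOf(rocCurve(sc, lb)), oracle_auc(sc, lb))

  set.seed(22)
  for (i in 1:40) {
    n <- sample(6:50, 1)
    lb <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    sc <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    expect_equal(aucOf(rocCurve(sc, lb)), oracle_auc(sc, lb))
  }

  # independent reference implementation on one instance
  set.seed(23)
  lb <- c(rep(TRUE, 30), rep(FALSE, 30))
  sc <- ifelse(lb, rnorm(60, 1), rnorm(60))
  expect_equal(aucOf(rocCurve(sc, lb)),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))))

  # labels independent of scores concentrate near 0.5
  set.seed(24)
  sc <- runif(2000)
  lb <- runif(2000) > 0.5
  expect_lt(abs(aucOf(rocCurve(sc, lb)) - 0.5), 0.05)

  expect_error(rocCurve(1:3, c(TRUE, TRUE, TRUE)), "degenerate")
})

test_that("cut-off optimization picks the accuracy-maximizing threshold", {
  # separable case: least stringent optimal threshold returned
  vals <- c(40, 45, 50, 20, 25, 34)
  labs <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  oc <- optimizeCutoff(vals, labs, "min-threshold")
  expect_equal(oc$threshold, 40)
  expect_equal(metricsVector(oc$metrics)[["acc"]], 1)

  # max-threshold direction (E-value-like)
  oc2 <- optimizeCutoff(c(1e-9, 1e-6, 0.5, 2), c(TRUE, TRUE, FALSE, FALSE),
                        "max-threshold")
  expect_equal(oc2$threshold, 1e-6)
  expect_equal(metricsVector(oc2$metrics)[["acc"]], 1)

  # sweep rows equal independently recomputed confusion metrics
  set.seed(25)
  vals <- round(runif(40, 0, 100))
  labs <- runif(40) > 0.5
  oc <- optimizeCutoff(vals, labs, "min-threshold")
  for (r in sample(nrow(oc$sweep), 5)) {
    t <- oc$sweep$threshold[r]
    pred <- vals >= t
    cm <- classMetrics(ConfusionCounts(sum(pred & labs), sum(pred & !labs),
                                       sum(!pred & !labs), sum(!pred & labs)))
    expect_equal(oc$sweep$acc[r], metricsVector(cm)[["acc"]])
    expect_equal(oc$sweep$sn[r], metricsVector(cm)[["sn"]])
  }
  # chosen accuracy dominates every swept threshold
  expect_true(all(oc$sweep$acc <= metricsVector(oc$metrics)[["acc"]] + 1e-12))

  # bimodal recovery: positives near 70, negatives near 20, 10% contamination
  set.seed(26)
  n <- 200
  labs <- rep(c(TRUE, FALSE), each = n / 2)
  vals <- ifelse(labs, rnorm(n, 70, 5), rnorm(n, 20, 5))
  flip <- sample(n, n / 10)
  vals[flip] <- ifelse(labs[flip], rnorm(length(flip), 20, 5),
                       rnorm(length(flip), 70, 5))
  oc <- optimizeCutoff(vals, labs, "min-threshold")
  expect_gt(oc$threshold, 20)
  expect_lt(oc$threshold, 70)
  expect_gte(metricsVector(oc$metrics)[["acc"]], 0.9)

  expect_error(optimizeCutoff(1:4, rep(TRUE, 4)), "degenerate")
})

test_that("residue-interval overlap reports fractions and cohort recovery", {
  ro <- residueOverlap(list(P1 = data.frame(start = 1, end = 10)),
                       list(P1 = c(5L, 10L, 20L)))
  expect_equal(ro$perProtein$fraction, 2 / 3)
  expect_true(ro$perProtein$recovered)

  ro <- residueOverlap(list(P1 = data.frame(start = c(1, 15),
                                            end = c(10, 25))),
                       list(P1 = c(5L, 10L, 20L)))
  expect_equal(ro$perProtein$fraction, 1)

  # no predicted interval: fraction 0, not recovered
  ro <- residueOverlap(list(), list(P1 = c(2L, 3L)))
  expect_equal(ro$perProtein$fraction, 0)
  expect_false(ro$perProtein$recovered)
  expect_equal(ro$sensitivity, 0)

  # zero-residue proteins are excluded with a warning
  expect_warning(
    ro <- residueOverlap(list(P1 = data.frame(start = 1, end = 5)),
                         list(P1 = c(2L), P2 = integer(0))),
    "excluded")
  expect_equal(ro$nProteins, 1L)

  # cohort: 3 of 4 recovered, 2 above the 70% bar
  ro <- residueOverlap(
    list(A = data.frame(start = 1, end = 50),
         B = data.frame(start = 1, end = 5),
         C = data.frame(start = 90, end = 99)),
    list(A = 1:10, B = c(3L, 30L, 40L), C = 1:5, D = c(7L)))
  expect_equal(ro$sensitivity, 0.5)
  expect_equal(ro$nHighOverlap, 1L)
})
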