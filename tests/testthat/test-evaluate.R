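test_that("confusion_metrics: perfect classifier and undefined flags", {
  for (k in c(1, 7)) {
    m <- confusion_metrics(k, 0, k, 0)
    expect_equal(unlist(m[c("acc", "sn", "sp", "precision", "f1", "mcc")]),
                 c(acc = 1, sn = 1, sp = 1, precision = 1, f1 = 1, mcc = 1))
  }
  m2 <- confusion_metrics(0, 0, 5, 0)
  expect_true(all(c("sn", "precision", "f1", "mcc") %in% m2$flags))
  expect_equal(m2$sn, 0)
  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
  expect_error(confusion_metrics(-1, 0, 1, 0), "nonnegative")
})

test_that("confusion_metrics invariants hold on random counts", {
  set.seed(15)
  for (i in 1:20) {
    cts <- rpois(4, 8) + c(1, 0, 1, 0)
    m <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(m$n, sum(cts))
    expect_true(all(unlist(m[c("acc", "sn", "sp", "precision", "f1")]) >= 0))
    expect_true(all(unlist(m[c("acc", "sn", "sp", "precision", "f1")]) <= 1))
    expect_gte(m$mcc, -1)
    expect_lte(m$mcc, 1)
    # f1 is the harmonic mean of precision and recall when both defined
    if (m$precision > 0 && m$sn > 0) {
      expect_equal(m$f1, 2 * m$precision * m$sn / (m$precision + m$sn),
                   tolerance = 1e-12)
    }
  }
})

test_that("roc_auc: separable, constant, and oracle-checked cases", {
  lab <- c(0, 0, 0, 1, 1, 1)
  expect_equal(roc_auc(c(1, 2, 3, 7, 8, 9), lab)$auc, 1)
  expect_equal(roc_auc(rep(2, 6), lab)$auc, 0.5)
  expect_equal(roc_auc(c(9, 8, 7, 1, 2, 3), lab)$auc, 0)

  # 6-point hand case with ties vs Mann-Whitney oracle
  sc <- c(0.3, 0.5, 0.5, 0.7, 0.5, 0.9)
  expect_equal(roc_auc(sc, lab)$auc, oracle_auc(sc, lab, 1), tolerance = 1e-12)

  # curve endpoints and monotonicity
  set.seed(4)
  sc2 <- rnorm(40)
  lab2 <- rep(0:1, 20)
  ra <- roc_auc(sc2, lab2)
  expect_equal(ra$roc$fpr[1], 0)
  expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
  expect_false(is.unsorted(ra$roc$fpr))
  expect_false(is.unsorted(ra$roc$tpr))
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("bootstrap_ci: width, bracketing, reproducibility, coverage", {
  df <- data.frame(score = c(rep(1, 10), rep(-1, 10)),
                   label = rep(c("b", "a"), each = 10))
  acc <- function(d) mean((d$score > 0) == (d$label == "b"))
  ci <- bootstrap_ci(acc, df, n_boot = 200, seed = 3)
  expect_equal(as.numeric(ci), c(1, 1))

  set.seed(8)
  df2 <- data.frame(score = rnorm(60), label = rep(c("a", "b"), 30))
  aucm <- function(d) roc_auc(d$score, d$label)$auc
  ci2 <- bootstrap_ci(aucm, df2, n_boot = 300, seed = 5)
  pt <- attr(ci2, "point")
  expect_lte(ci2[1], pt)
  expect_gte(ci2[2], pt)
  expect_identical(unname(bootstrap_ci(aucm, df2, n_boot = 300, seed = 5)),
                   unname(ci2))

  # coverage: 95% CI for accuracy of Bernoulli(0.8) predictions, n = 100
  set.seed(99)
  cover <- sum(sapply(1:100, function(r) {
    d <- data.frame(correct = rbinom(100, 1, 0.8))
    ci <- bootstrap_ci(function(x) mean(x$correct), d, n_boot = 200,
                       seed = 1000 + r)
    ci[1] <= 0.8 && 0.8 <= ci[2]
  }))
  expect_gte(cover, 90)
})

test_that("evaluate_classifier assembles a coherent report", {
  set.seed(1)
  bl_tr <- rbind(matrix(rnorm(60), 20), matrix(rnorm(60, 4), 20))
  y_tr <- factor(rep(c("healthy", "disease"), each = 20),
                 levels = c("healthy", "disease"))
  clf <- train_svm(bl_tr, y_tr, seed = 1)
  set.seed(2)
  bl_te <- rbind(matrix(rnorm(30), 10), matrix(rnorm(30, 4), 10))
  y_te <- factor(rep(c("healthy", "disease"), each = 10),
                 levels = c("healthy", "disease"))
  rep <- evaluate_classifier(clf, bl_te, y_te, n_boot = 100, seed = 7)
  expect_equal(sum(rep$counts), 20)
  expect_gte(rep$auc, 0.95)
  for (nm in names(rep$ci)) {
    expect_lte(rep$ci[[nm]][1], rep$ci[[nm]][2])
  }
})
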