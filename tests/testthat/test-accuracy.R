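test_that("contingency cells partition the cohort", {
  pred <- c(rep(TRUE, 25), rep(FALSE, 42))
  truth <- c(rep(TRUE, 18), rep(FALSE, 7), rep(FALSE, 42))
  tab <- build_contingency(pred, truth)
  expect_equal(unclass(tab)[c("tp", "fp", "fn", "tn")],
               list(tp = 18L, fp = 7L, fn = 0L, tn = 42L))
  expect_equal(tab$tp + tab$fp + tab$fn + tab$tn, 67L)
  # relabelling symmetry: flipping predictions swaps tp<->fn and fp<->tn
  flipped <- build_contingency(!pred, truth)
  expect_equal(c(flipped$tp, flipped$fp, flipped$fn, flipped$tn),
               c(tab$fn, tab$tn, tab$tp, tab$fp))
  all_neg <- build_contingency(rep(FALSE, 5), rep(FALSE, 5))
  expect_equal(c(all_neg$tp, all_neg$fp, all_neg$fn, all_neg$tn),
               c(0L, 0L, 0L, 5L))
})

test_that("accuracy metrics reproduce the reference strata at printed precision", {
  cases <- list(
    all    = list(tab = c(18, 7, 0, 42), spec = 0.857, ppv = 0.720),
    lambda = list(tab = c(7, 2, 0, 20), spec = 0.909, ppv = 0.778),
    kappa  = list(tab = c(11, 5, 0, 22), spec = 0.815, ppv = 0.688)
  )
  for (s in names(cases)) {
    tab <- do.call(contingency_table, as.list(cases[[s]]$tab))
    m <- accuracy_metrics(tab, stratum = s)$metrics
    est <- setNames(m$estimate, m$metric)
    expect_equal(est[["sensitivity"]], 1)
    expect_equal(est[["npv"]], 1)
    expect_equal(round(est[["specificity"]], 3), cases[[s]]$spec)
    expect_equal(round(est[["ppv"]], 3), cases[[s]]$ppv)
  }
})

test_that("a perfect classifier scores 1 on all four metrics", {
  m <- accuracy_metrics(contingency_table(5, 0, 0, 9))$metrics
  expect_equal(m$estimate, rep(1, 4))
})

test_that("exact intervals contain the estimate and tighten with n", {
  m <- accuracy_metrics(contingency_table(18, 7, 0, 42))$metrics
  ok <- !is.na(m$estimate)
  expect_true(all(m$lower[ok] <= m$estimate[ok] & m$estimate[ok] <= m$upper[ok]))
  # same proportion, larger denominator -> narrower interval
  w1 <- with(accuracy_metrics(contingency_table(8, 2, 2, 8))$metrics,
             upper[1] - lower[1])
  w2 <- with(accuracy_metrics(contingency_table(80, 20, 20, 80))$metrics,
             upper[1] - lower[1])
  expect_lt(w2, w1)
})

test_that("zero-denominator metrics are undefined, never 0 or 1", {
  m <- accuracy_metrics(contingency_table(0, 0, 0, 10))$metrics
  est <- setNames(m$estimate, m$metric)
  expect_true(is.na(est[["sensitivity"]])) # no diseased subjects
  expect_true(is.na(est[["ppv"]]))         # no positive predictions
  expect_equal(est[["specificity"]], 1)
  expect_error(contingency_table(0, 0, 0, 0))
})

test_that("ROC handles separation, pure ties, and the enumerated example", {
  sep <- roc_curve(c(10, 9, 8, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$auc, 1)
  tied <- roc_curve(rep(3, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(tied$auc, 0.5)
  # diseased {3, 5} vs non-diseased {1, 4}: 3 of 4 pairs concordant
  ex <- roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ex$auc, 0.75)
  expect_equal(oracle_auc_pairs(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "non-diseased")
})

test_that("ROC points are monotone and anchored at (0,0) and (1,1)", {
  set.seed(401)
  sc <- round(rexp(40, 0.2), 1)
  tr <- runif(40) < 0.4
  roc <- roc_curve(sc, tr)
  p <- roc$points
  expect_true(all(diff(p$tpr) <= 0)) # sorted by increasing threshold
  expect_true(all(diff(p$fpr) <= 0))
  expect_equal(c(p$fpr[1], p$tpr[1]), c(1, 1))
  expect_equal(c(p$fpr[nrow(p)], p$tpr[nrow(p)]), c(0, 0))
})

test_that("trapezoid, rank statistic and pair enumeration agree, also vs pROC", {
  skip_if_not_installed("pROC")
  set.seed(402)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    sc <- sample(round(rnorm(n, 5, 2), sample(0:1, 1))) # induce ties
    tr <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    roc <- roc_curve(sc, tr)
    expect_equal(roc$auc, auc_trapezoid(roc), tolerance = 1e-12)
    expect_equal(roc$auc, oracle_auc_pairs(sc, tr), tolerance = 1e-12)
    proc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = tr, predictor = sc, direction = "<", quiet = TRUE
    )))
    expect_equal(roc$auc, proc_auc, tolerance = 1e-10)
  }
})

test_that("stratified tables add cell-wise and reports are order-invariant", {
  ch <- generate_cohort(seed = 31)
  preds <- apply_rule(ch)
  sa <- stratified_accuracy(preds)
  for (cell in c("tp", "fp", "fn", "tn")) {
    expect_equal(sa$all$report$table[[cell]],
                 sa$kappa$report$table[[cell]] + sa$lambda$report$table[[cell]])
  }
  perm <- preds[sample(nrow(preds)), ]
  sa2 <- stratified_accuracy(perm)
  expect_equal(sa2$all$report$metrics, sa$all$report$metrics)
})

test_that("a single-stratum cohort yields one stratified report equal to overall", {
  df <- make_patient_df(4)
  df$lc_type <- "kappa"
  preds <- apply_rule(as_cohort(df))
  expect_message(sa <- stratified_accuracy(preds), "lambda")
  expect_null(sa$lambda)
  expect_equal(sa$kappa$report$metrics, sa$all$report$metrics)
})

test_that("the lambda rule's operating point lies on its quotient ROC", {
  # for lambda the rule is a pure threshold at quotient > 2, so its
  # (FPR, TPR) must be an operating point of the quotient ROC
  ch <- generate_cohort(seed = 32)
  preds <- apply_rule(ch)
  lam <- preds[preds$lc_type == "lambda", ]
  roc <- roc_curve(lam$quotient, lam$is_cn)
  tab <- build_contingency(lam$positive, lam$is_cn)
  sens <- tab$tp / (tab$tp + tab$fn)
  fpr <- tab$fp / (tab$fp + tab$tn)
  t0 <- max(lam$quotient[lam$quotient <= 2])
  pt <- roc$points[roc$points$threshold == t0, ]
  expect_equal(c(pt$fpr, pt$tpr), c(fpr, sens))
})
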