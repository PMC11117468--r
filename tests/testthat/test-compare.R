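test_that("group summaries use type-7 quartiles and behave under duplication", {
  ch <- generate_cohort(seed = 51)
  s <- summarize_groups(ch)
  expect_equal(sum(s$n[s$variable == "egfr"]), nrow(ch))
  expect_true(all(s$iqr >= 0))
  # single-value group
  df <- make_patient_df(1)
  s1 <- summarize_groups(as_cohort(df))
  expect_equal(s1$median[s1$variable == "egfr"], df$egfr)
  expect_equal(s1$iqr[s1$variable == "egfr"], 0)
  # duplicating every row leaves medians unchanged
  df2 <- tibble::as_tibble(generate_cohort(seed = 51))
  df2 <- rbind(df2, transform(df2, id = paste0(id, "b")))
  s2 <- summarize_groups(as_cohort(df2, provenance = "synthetic"))
  expect_equal(s2$median, s$median)
})

test_that("Kruskal-Wallis matches a first-principles rank computation", {
  expect_equal(kruskal_wallis(c(1, 2, 3, 4, 5, 6),
                              rep(c("a", "b"), each = 3))$statistic,
               oracle_kw_h(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3)),
               tolerance = 1e-12)
  set.seed(501)
  for (i in 1:20) {
    vals <- round(rnorm(30), 1) # ties likely
    grp <- sample(letters[1:3], 30, replace = TRUE)
    if (length(unique(grp)) < 2) next
    kw <- kruskal_wallis(vals, grp)
    expect_equal(kw$statistic, oracle_kw_h(vals, grp), tolerance = 1e-12)
    expect_true(kw$tie_correction <= 1 && kw$tie_correction > 0)
  }
})

test_that("rank statistics are invariant under strictly monotone transforms", {
  set.seed(502)
  vals <- rexp(40)
  grp <- sample(c("a", "b", "c", "d"), 40, replace = TRUE)
  expect_equal(kruskal_wallis(vals, grp)$statistic,
               kruskal_wallis(log(vals), grp)$statistic, tolerance = 1e-12)
  expect_equal(dunn_posthoc(vals, grp)$z,
               dunn_posthoc(exp(vals), grp)$z, tolerance = 1e-12)
})

test_that("a large shift separates groups decisively", {
  set.seed(503)
  a <- rnorm(20); b <- rnorm(20) + 50
  expect_lt(kruskal_wallis(c(a, b), rep(1:2, each = 20))$p_value, 1e-3)
})

test_that("degenerate all-tied input is flagged with H = 0, p = 1", {
  kw <- kruskal_wallis(rep(7, 9), rep(1:3, each = 3))
  expect_true(kw$degenerate)
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p_value, 1)
  d <- dunn_posthoc(rep(7, 9), rep(1:3, each = 3))
  expect_equal(d$z, rep(0, 3))
  expect_equal(d$p_raw, rep(1, 3))
})

test_that("with two groups Dunn z-squared equals the Kruskal-Wallis H", {
  set.seed(504)
  for (i in 1:20) {
    vals <- round(rnorm(25), sample(0:1, 1))
    grp <- sample(c("x", "y"), 25, replace = TRUE)
    if (length(unique(grp)) < 2) next
    z <- dunn_posthoc(vals, grp)$z
    h <- kruskal_wallis(vals, grp)$statistic
    expect_equal(z^2, h, tolerance = 1e-10)
  }
})

test_that("Benjamini-Hochberg follows the step-up definition", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  set.seed(505)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))^2
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-15)
    expect_true(all(adj >= p & adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p)) # order-preserving
  }
})

test_that("t-test and ANOVA behave on identities and degenerate input", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  tt <- two_sample_t(x, x)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  # classical identity: pooled t^2 equals one-way F for two groups
  set.seed(506)
  a <- rnorm(12); b <- rnorm(15, 1)
  tt2 <- two_sample_t(a, b, pooled = TRUE)
  f <- one_way_anova(c(a, b), rep(1:2, c(12, 15)))
  expect_equal(tt2$statistic^2, f$statistic, tolerance = 1e-10)
  expect_equal(tt2$p_value, f$p_value, tolerance = 1e-10)
})

test_that("the quotient separates cast nephropathy from ALA and Others", {
  ch <- generate_cohort(seed = 507)
  cg <- compare_groups(ch, "quotient")
  expect_lt(cg$omnibus$p_value, 0.05)
  pw <- cg$pairwise
  key <- paste(pw$group1, pw$group2)
  expect_lt(pw$p_adjusted[key == "CN ALA"], 0.05)
  expect_lt(pw$p_adjusted[key == "CN Others"], 0.05)
  expect_true(all(pw$p_adjusted >= pw$p_raw))
})

test_that("creatinine is far higher in cast nephropathy than in other disease", {
  # at the published cohort size the skewed creatinine still separates;
  # significance tightens once the cohort is scaled up
  ch <- generate_cohort(seed = 508)
  is_cn <- ch$histology == "cast_nephropathy"
  tt <- two_sample_t(ch$serum_creatinine[is_cn], ch$serum_creatinine[!is_cn])
  expect_gt(tt$statistic, 0)
  expect_lt(tt$p_value, 0.05)
  big <- generate_cohort(cohort_spec(n_scale = 5L), seed = 508)
  is_cn <- big$histology == "cast_nephropathy"
  tt2 <- two_sample_t(big$serum_creatinine[is_cn], big$serum_creatinine[!is_cn])
  expect_lt(tt2$p_value, 0.001)
  # eGFR separates in the opposite direction
  tt3 <- two_sample_t(big$egfr[is_cn], big$egfr[!is_cn])
  expect_lt(tt3$statistic, 0)
  expect_lt(tt3$p_value, 1e-4)
})
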