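test_that("the Shapiro-Wilk wrapper validates its input", {
  r <- shapiro_wilk(c(0.1, 0.5, 0.3, 0.8, 0.2))
  expect_true(r$statistic > 0 && r$statistic <= 1)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  expect_error(shapiro_wilk(rep(0.7, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "sample size")
})

test_that("the t-test degenerates and separates as expected", {
  a <- c(1, 2, 3, 4)
  r <- students_t(a, a)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  base <- c(0, 0, 0, 1, 1, 1)
  rs <- students_t(base + 10, base)
  expect_lt(rs$p_value, 1e-6)

  # symmetric under sample swap
  set.seed(1)
  x <- rnorm(10); y <- rnorm(10, 0.5)
  expect_equal(students_t(x, y)$p_value, students_t(y, x)$p_value)
  expect_equal(students_t(x, y, var_equal = TRUE)$p_value,
               t.test(x, y, var.equal = TRUE)$p.value)
})

test_that("the U test is rank-based: invariant under monotone transforms", {
  set.seed(4)
  a <- runif(10); b <- runif(10, 0.3)
  r1 <- mann_whitney_u(a, b)
  r2 <- mann_whitney_u(exp(3 * a), exp(3 * b))
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, r2$statistic)
  ri <- mann_whitney_u(a, a)
  expect_gte(ri$p_value, 0.9)
  expect_error(mann_whitney_u(numeric(0), a), "non-empty")
})

test_that("the normality gate selects the test the protocol prescribes", {
  set.seed(6)
  gauss_a <- rnorm(10, 0.8, 0.02)
  gauss_b <- rnorm(10, 0.7, 0.02)
  rg <- select_and_compare(gauss_a, gauss_b, metric = "demo")
  expect_identical(rg$test, "t")
  expect_identical(rg$decision, "rejected")

  tied <- c(rep(0.7, 8), 0.8, 0.9)       # heavy ties: normality rejected
  rt <- select_and_compare(tied, gauss_b)
  expect_lt(shapiro_wilk(tied)$p_value, 0.05)
  expect_identical(rt$test, "U")

  distinct <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.55, 0.45, 0.35, 0.25, 0.15)
  self_cmp <- select_and_compare(distinct, distinct)
  expect_identical(self_cmp$decision, "retained")

  # a constant sample (e.g. specificity 1 in every fold) cannot be normal:
  # the gate falls through to the rank test instead of erroring
  rc <- select_and_compare(rep(1, 10), gauss_b)
  expect_identical(rc$test, "U")
  expect_true(is.na(rc$shapiro_p_a))
  expect_identical(rc$decision, "rejected")
})

test_that("Welch p-values reproduce the published PH2 mean-comparison table", {
  # the printed exponents are read as negative powers of ten
  t9 <- load_paper_fold_table("PH2", "complex")
  t10 <- load_paper_fold_table("PH2", "real")
  printed <- c(f1_score = 7.71763e-8, precision = 1.13570e-7,
               recall_sensitivity = 6.08852e-6, specificity = 4.11085e-3)
  for (m in names(printed)) {
    p <- students_t(t9[[m]], t10[[m]])$p_value
    expect_equal(p, printed[[m]], tolerance = 0.005)
  }
  # the pooled-variance variant does not reproduce the published values,
  # which is why Welch is the default
  pooled <- students_t(t9$f1_score, t10$f1_score, var_equal = TRUE)$p_value
  expect_gt(abs(pooled - 7.71763e-8) / 7.71763e-8, 0.5)
})

test_that("printed normality rows reconcile with recomputation up to a column shift", {
  # The published PH2/Pascal tables print the F1/Precision/Recall normality
  # p-values cyclically shifted by one column (printed F1 slot holds the
  # Precision value, and so on); Accuracy/Specificity are aligned. Under
  # that correction 24 of the 30 printed values reproduce to 1e-3 from the
  # printed fold columns; the remainder depend on unprinted precision or on
  # mis-printed fold columns and reproduce under no alignment.
  mets <- c("f1_score", "precision", "recall_sensitivity", "accuracy",
            "specificity")
  shifted <- c("PH2_complex", "PH2_real", "PASCAL_complex", "PASCAL_real")
  irreconcilable <- list(
    ISIC2017_complex = c("f1_score", "recall_sensitivity", "specificity"),
    ISIC2017_real = "f1_score",
    PH2_complex = "accuracy",       # printed fold column duplicates Recall
    PH2_real = "recall_sensitivity" # rounding ties shift the fold p-value
  )
  for (nm in names(printed_normality)) {
    ids <- strsplit(nm, "_")[[1]]
    tbl <- load_paper_fold_table(ids[1], ids[2])
    rec <- vapply(mets, function(m) shapiro_wilk(tbl[[m]])$p_value,
                  numeric(1))
    map <- if (nm %in% shifted) c(2, 3, 1, 4, 5) else 1:5
    d <- abs(printed_normality[[nm]] - rec[map])
    reconcile <- setdiff(mets, irreconcilable[[nm]])
    expect_true(all(d[reconcile] < 1e-3),
                info = paste(nm, "worst", signif(max(d[reconcile]), 3)))
  }
})

test_that("ROC distance has the ideal-corner geometry", {
  expect_equal(roc_distance(1, 1), 0)
  expect_equal(roc_distance(0, 0), sqrt(2))
  expect_equal(roc_distance(1, 0), 1)
  # decreasing in sensitivity and specificity
  d <- roc_distance(c(0.5, 0.6, 0.7), 0.8)
  expect_true(all(diff(d) < 0))
  d2 <- roc_distance(0.8, c(0.5, 0.6, 0.7))
  expect_true(all(diff(d2) < 0))
  expect_true(all(roc_distance(runif(20), runif(20)) <= sqrt(2)))
  expect_error(roc_distance(1.2, 0.5), "\\[0, 1\\]")
})

test_that("relative superiority is the percent distance reduction", {
  expect_equal(relative_superiority(0.3, 0.3), 0)
  expect_equal(relative_superiority(0, 0.5), 100)
  expect_equal(relative_superiority(0.26127, 0.36022), 27.47,
               tolerance = 0.001)
  expect_error(relative_superiority(0.1, 0), "d_worse")
})

test_that("reports order the structures by ROC distance on all datasets", {
  distances <- c(ISIC2017 = 0.26127, PH2 = 0.31681, PASCAL = 0.29447)
  for (ds in names(distances)) {
    rep <- build_report(load_paper_fold_table(ds, "complex"),
                        load_paper_fold_table(ds, "real"))
    expect_identical(rep$superior_structure, "complex")
    expect_lt(rep$roc$complex$distance, rep$roc$real$distance)
    expect_equal(rep$roc$complex$distance, distances[[ds]], tolerance = 1e-4)
    expect_length(rep$results, 5)
  }

  # a table compared with itself: every H0 retained, superiority zero
  t6 <- load_paper_fold_table("ISIC2017", "complex")
  self_rep <- build_report(t6, t6)
  expect_true(all(vapply(self_rep$results, `[[`, character(1),
                         "decision") == "retained"))
  expect_equal(self_rep$relative_superiority, 0)

  expect_error(build_report(t6, load_paper_fold_table("PH2", "real")),
               "different datasets")
})

test_that("reports serialise to JSON and text", {
  rep <- build_report(load_paper_fold_table("PH2", "complex"),
                      load_paper_fold_table("PH2", "real"))
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".txt")
  on.exit(unlink(c(jf, tf)))
  write_report(rep, jf, tf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$roc$complex$distance, rep$roc$complex$distance,
               tolerance = 1e-12)
  expect_identical(parsed$superior_structure, "complex")
  expect_true(any(grepl("ROC distance", readLines(tf))))
})
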