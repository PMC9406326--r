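test_that("stratified folds preserve class ratios and partition the data", {
  labels <- c(rep(0L, 160), rep(1L, 40))
  folds <- kfold_split(labels, k = 10, seed = 1)
  expect_length(folds, 10)
  for (f in folds) {
    expect_identical(sum(labels[f$val] == 0), 16L)
    expect_identical(sum(labels[f$val] == 1), 4L)
    expect_length(intersect(f$train, f$val), 0)
  }
  # every record validated exactly once
  all_val <- sort(unlist(lapply(folds, `[[`, "val")))
  expect_identical(all_val, seq_along(labels))

  # two balanced folds of two
  f2 <- kfold_split(c(0L, 0L, 1L, 1L), k = 2, seed = 3)
  expect_identical(sort(c(f2[[1]]$val, f2[[2]]$val)), 1:4)
  expect_length(f2[[1]]$val, 2)

  # determinism
  expect_identical(kfold_split(labels, 10, seed = 7),
                   kfold_split(labels, 10, seed = 7))
  expect_error(kfold_split(c(rep(0L, 30), rep(1L, 5)), k = 10),
               "stratification")
})

test_that("the complex-corrected Adam step behaves as derived by hand", {
  cfg <- training_config()
  # real parameter: the bias-corrected first step has magnitude ~ lr
  p <- list(w = 0.5)
  st <- complex_adam_step(p, list(w = 3.2), NULL, cfg)
  expect_equal(abs(st$params$w - 0.5), cfg$learning_rate, tolerance = 1e-6)

  # zero gradient on a complex parameter leaves it unchanged
  pc <- list(w = list(re = 1.5, im = -0.5))
  stc <- complex_adam_step(pc, list(w = list(re = 0, im = 0)), NULL, cfg)
  expect_equal(stc$params$w, pc$w)

  # one step from zero state with g = 1 + 1i: shared modulus normalisation
  # gives -lr / sqrt(2) on each component
  pc2 <- list(w = list(re = 0, im = 0))
  st2 <- complex_adam_step(pc2, list(w = list(re = 1, im = 1)), NULL, cfg)
  expect_equal(st2$params$w$re, -0.001 / sqrt(2), tolerance = 1e-6)
  expect_equal(st2$params$w$im, -0.001 / sqrt(2), tolerance = 1e-6)

  # with constant gradient the step magnitude approaches lr as t grows
  p3 <- list(w = 0); s3 <- NULL
  prev <- 0
  for (t in 1:200) {
    st3 <- complex_adam_step(p3, list(w = 1), s3, cfg)
    delta <- abs(st3$params$w - p3$w)
    p3 <- st3$params; s3 <- st3$state
    prev <- delta
  }
  expect_equal(prev, cfg$learning_rate, tolerance = 1e-4)

  expect_error(complex_adam_step(list(w = 0), list(w = NaN), NULL, cfg),
               "non-finite")
})

test_that("confusion metrics follow their defining ratios", {
  perfect <- confusion_metrics(10, 0, 10, 0)
  expect_equal(unlist(perfect[1:5], use.names = FALSE), rep(1, 5))

  m <- confusion_metrics(9, 1, 6, 2)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall_sensitivity, 9 / 11)
  expect_equal(m$f1_score, 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11))
  expect_equal(m$accuracy, 15 / 18)
  expect_equal(m$specificity, 6 / 7)
  expect_length(m$flagged, 0)

  z <- confusion_metrics(0, 0, 10, 5)
  expect_equal(z$precision, 0)
  expect_true("precision" %in% z$flagged)
  expect_equal(z$recall_sensitivity, 0)
  expect_equal(z$specificity, 1)

  expect_error(confusion_metrics(0, 0, 0, 0), "degenerate")

  # accuracy decomposes into the prevalence-weighted mean of sensitivity
  # and specificity
  set.seed(2)
  for (i in 1:25) {
    cts <- rmultinom(1, 40, rep(0.25, 4))
    if (cts[1] + cts[4] == 0 || cts[3] + cts[2] == 0) next
    mm <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    P <- cts[1] + cts[4]; N <- cts[3] + cts[2]
    expect_equal(mm$accuracy,
                 (P * mm$recall_sensitivity + N * mm$specificity) / (P + N))
  }
})

test_that("fold training is reproducible and actually minimises the loss", {
  prof <- dataset_profile("smoke", 16, 16, image_size = 16,
                          separability = 1, seed = 4)
  man <- generate_lesion_dataset(prof)
  X <- array(0, c(16, 16, 3, 32))
  for (i in 1:32) X[, , , i] <- normalize_image(man$images[[i]])
  y <- man$labels
  pair <- default_architecture_pair(input_size = 16)
  cfg <- training_config(epochs = 12, seed = 9)

  for (dom in c("complex", "real")) {
    net <- build_network(pair[[dom]], seed = 6)
    tr <- train_fold(net, X, y, cfg)
    expect_length(tr$loss_trace, 12)
    expect_lt(tr$loss_trace[12], tr$loss_trace[1])

    tr2 <- train_fold(build_network(pair[[dom]], seed = 6), X, y, cfg)
    expect_identical(tr$loss_trace, tr2$loss_trace)

    frozen <- train_fold(build_network(pair[[dom]], seed = 6), X, y,
                         training_config(learning_rate = 0, epochs = 2,
                                         seed = 9))
    ref <- build_network(pair[[dom]], seed = 6)
    expect_identical(cvfair:::.net_params(frozen$network),
                     cvfair:::.net_params(ref))
  }
})

test_that("the paired experiment separates classes it should and not ones it cannot", {
  pair <- default_architecture_pair(input_size = 32, in_channels = 1)
  cfg <- training_config(epochs = 50, k = 4, seed = 11)

  hard <- generate_scalogram_dataset(
    dataset_profile("sep0", 40, 40, image_size = 32, separability = 0,
                    seed = 12))
  r0 <- run_experiment(hard, pair$complex, pair$real, cfg)
  expect_gte(mean(r0$complex$accuracy), 0.35)
  expect_lte(mean(r0$complex$accuracy), 0.65)
  expect_gte(mean(r0$real$accuracy), 0.35)
  expect_lte(mean(r0$real$accuracy), 0.65)

  easy <- generate_scalogram_dataset(
    dataset_profile("sep1", 40, 40, image_size = 32, separability = 1,
                    seed = 12))
  r1 <- run_experiment(easy, pair$complex, pair$real, cfg)
  expect_gte(mean(r1$complex$accuracy), 0.9)
  expect_gte(mean(r1$real$accuracy), 0.9)

  # contract: both structures trained on identical splits, tables well formed
  expect_identical(r1$folds, kfold_split(easy$labels, k = 4, seed = 11))
  for (tbl in list(r1$complex, r1$real)) {
    expect_s3_class(tbl, "fold_metric_table")
    expect_identical(nrow(tbl), 4L)
    vals <- unlist(tbl[-1])
    expect_true(all(vals >= 0 & vals <= 1))
  }
})
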