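test_that("fingerprint_length matches hand-propagated shape arithmetic", {
  # default stack on the full-size input plane: 20x160 -> 10x80 -> 5x40 ->
  # 2x20, 64 filters => 2560 (computed by hand, not by the package)
  cfg <- classifier_config(n_classes = 5)
  expect_identical(fingerprint_length(cfg, c(20, 160, 3)), 2560L)

  # tiny profile: 4x32 -> 2x16 -> 1x8, 16 filters => 128
  expect_identical(fingerprint_length(tiny_config(2), c(4, 32, 2)), 128L)

  expect_error(fingerprint_length(tiny_config(2), c(2, 32, 1)),
               "configuration error")
  # dimensionality reduction premise: m < eta * T * |C|
  for (ch in 1:4) {
    expect_lt(fingerprint_length(classifier_config(5), c(20, 160, ch)),
              20 * 160 * ch)
  }
})

test_that("untrained model emits valid probability vectors", {
  cfg <- tiny_config(3)
  model <- build_classifier(cfg, c(4, 32, 2))
  x <- array(0, dim = c(4, 32, 2))
  p <- predict(model, list(x))
  expect_identical(dim(p), c(3L, 1L))
  expect_equal(sum(p), 1)
  expect_true(all(is.finite(p)) && all(p >= 0))

  set.seed(1)
  xr <- array(rnorm(4 * 32 * 2 * 7), dim = c(4, 32, 2, 7))
  pr <- predict(model, xr)
  expect_equal(unname(colSums(pr)), rep(1, 7))
  expect_true(all(is.finite(pr)) && all(pr >= 0))
})

test_that("training separates a 2-subject synthetic cohort and is seed-reproducible", {
  cohort <- session1(tiny_cohort(seed = 21))
  p <- tiny_params()
  xs <- list(); ys <- integer(0)
  for (r in cohort) {
    inp <- build_inputs(r, r$channel_names, p, max_inputs = 60)
    xs <- c(xs, inp)
    ys <- c(ys, rep(match(r$subject_id, c("S01", "S02")) - 1L, length(inp)))
  }
  cfg <- tiny_config(2, seed = 5)
  m1 <- train_classifier(build_classifier(cfg, dim(xs[[1]])), xs, ys,
                         epochs = 150)
  expect_gte(tail(m1$history$accuracy, 1), 0.95)

  m2 <- train_classifier(build_classifier(cfg, dim(xs[[1]])), xs, ys,
                         epochs = 150)
  expect_equal(tail(m1$history$loss, 1), tail(m2$history$loss, 1))
  expect_equal(m1$weights, m2$weights)

  expect_error(train_classifier(build_classifier(cfg, dim(xs[[1]])), xs,
                                rep(c(0L, 2L), length.out = length(xs))),
               "labels")
  expect_error(train_classifier(build_classifier(cfg, dim(xs[[1]])), xs,
                                rep(0L, length(xs))),
               "zero samples")
})

test_that("split_fingerprint exposes only the feature stack and composes with the head", {
  cfg <- tiny_config(2, seed = 9)
  model <- build_classifier(cfg, c(4, 32, 2))
  model$trained <- TRUE                     # silence the untrained note
  f <- split_fingerprint(model)
  expect_identical(f$fingerprint_len, 128L)
  expect_false(any(grepl("^W1$|^W2$", names(f))))
  expect_length(f$conv_weights, 4L)         # two conv blocks: W, b each

  set.seed(2)
  x <- array(rnorm(4 * 32 * 2 * 3), dim = c(4, 32, 2, 3))
  feat <- fingerprint_inputs(f, x)
  expect_identical(dim(feat), c(128L, 3L))
  expect_true(all(feat >= 0))               # post-ReLU/pool activations

  # determinism at inference
  expect_identical(feat, fingerprint_inputs(f, x))

  # composition identity: full model prediction == head applied to features
  w <- model$weights
  h <- pmax(w[[5]] %*% feat + w[[6]], 0)
  logits <- w[[7]] %*% h + w[[8]]
  pref <- apply(logits, 2, function(z) { e <- exp(z - max(z)); e / sum(e) })
  expect_equal(unname(predict(model, x)), unname(pref), tolerance = 1e-12)
})

test_that("fingerprint_sample aggregates per-window fingerprints by mean", {
  rec <- random_recording(n_channels = 2L, n_samples = 200L, seed = 3)
  p <- tiny_params()                        # Gamma = 56
  model <- build_classifier(tiny_config(2), c(4, 32, 2))
  model$trained <- TRUE
  f <- split_fingerprint(model)

  fp_all <- fingerprint_sample(f, rec, rec$channel_names, p,
                               aggregation = "none")
  fp_mean <- fingerprint_sample(f, rec, rec$channel_names, p)
  expect_equal(as.numeric(fp_mean), rowSums(fp_all) / ncol(fp_all))
  expect_identical(attr(fp_mean, "model_version"), f$model_version)

  # a record spanning exactly Gamma yields one offset: mean == the window
  rec1 <- eeg_recording(rec$data[, 1:56], 160, rec$channel_names)
  fp1 <- fingerprint_sample(f, rec1, rec$channel_names, p)
  fpn <- fingerprint_sample(f, rec1, rec$channel_names, p, aggregation = "none")
  expect_identical(ncol(fpn), 1L)
  expect_equal(as.numeric(fp1), as.numeric(fpn[, 1]))
})

test_that("trained fingerprints cluster within subjects (rank separation)", {
  cohort <- tiny_cohort(seed = 31)
  p <- tiny_params()
  fit <- train_cohort_model(session1(cohort), cohort[[1]]$channel_names, p,
                            config = tiny_config(2), seed = 7, epochs = 120,
                            max_inputs = 80)
  f <- split_fingerprint(fit$model)
  s2 <- Filter(function(r) identical(r$session, 2L), cohort)
  fps <- lapply(s2, function(r) {
    fingerprint_sample(f, r, r$channel_names, p, aggregation = "none",
                       max_inputs = 20)
  })
  genuine <- impostor <- c()
  for (i in 1:20) {
    for (j in 1:20) {
      if (j <= i) next
      genuine <- c(genuine,
                   fingerprint_distance(fps[[1]][, i], fps[[1]][, j]),
                   fingerprint_distance(fps[[2]][, i], fps[[2]][, j]))
    }
    impostor <- c(impostor, fingerprint_distance(fps[[1]][, i], fps[[2]][, i]))
  }
  expect_lt(stats::wilcox.test(genuine, impostor,
                               alternative = "less")$p.value, 0.01)
})
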