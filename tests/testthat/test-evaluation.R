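toy_sep <- list(genuine = c(0.1, 0.2), impostor = c(0.3, 0.4))

test_that("far_frr implements the rate definitions", {
  expect_equal(far_frr(toy_sep, 0.25), c(far = 0, frr = 0))
  expect_equal(far_frr(toy_sep, 0.05), c(far = 0, frr = 1))
  expect_equal(far_frr(toy_sep, 0.5), c(far = 1, frr = 0))
  # boundary accepts: threshold exactly at an impostor distance counts it
  expect_equal(far_frr(toy_sep, 0.3), c(far = 0.5, frr = 0))
  expect_error(far_frr(list(genuine = 1, impostor = numeric(0)), 1),
               "undefined rate")
})

test_that("det_curve covers achievable rates and matches brute force", {
  cv <- det_curve(toy_sep)
  expect_true(any(cv$far == 0 & cv$frr == 0))

  # identical distributions: acceptance fraction identity, EER ~ 0.5
  same <- list(genuine = c(0.1, 0.2, 0.3), impostor = c(0.1, 0.2, 0.3))
  cvs <- det_curve(same)
  expect_equal(cvs$far, 1 - cvs$frr)
  expect_equal(eer_threshold(cvs)$eer, 0.5)

  # brute-force oracle on a random 20-trial toy
  set.seed(42)
  toy <- list(genuine = runif(10), impostor = runif(10))
  cv2 <- det_curve(toy)
  for (i in seq_len(nrow(cv2))) {
    t <- cv2$threshold[i]
    expect_equal(cv2$far[i], sum(toy$impostor <= t) / 10)
    expect_equal(cv2$frr[i], sum(toy$genuine > t) / 10)
  }
  # monotone in threshold
  expect_true(all(diff(cv2$far) >= 0))
  expect_true(all(diff(cv2$frr) <= 0))
})

test_that("eer_threshold matches an exhaustive scan and handles toys", {
  expect_equal(eer_threshold(det_curve(toy_sep))$eer, 0)

  set.seed(7)
  toy <- list(genuine = rnorm(10, 1), impostor = rnorm(10, 2))
  cv <- det_curve(toy)
  pick <- eer_threshold(cv)
  gaps <- abs(cv$far - cv$frr)
  expect_equal(abs(pick$far - pick$frr), min(gaps))
  # tie-break toward the lowest qualifying threshold
  expect_equal(pick$threshold, min(cv$threshold[gaps == min(gaps)]))
  expect_equal(pick$eer, (pick$far + pick$frr) / 2)

  # rates are scale invariant: duplicating every trial changes nothing
  dup <- lapply(toy, rep, 2)
  expect_equal(eer_threshold(det_curve(dup))[c("threshold", "eer")],
               pick[c("threshold", "eer")])
})

test_that("FAR/FRR monotonicity holds on random trial sets", {
  set.seed(3)
  for (i in 1:20) {
    trials <- list(genuine = rgamma(sample(5:30, 1), 2, 8),
                   impostor = rgamma(sample(5:30, 1), 3, 4))
    grid <- sort(c(0, runif(15), 2))
    rates <- vapply(grid, function(t) far_frr(trials, t), numeric(2))
    expect_true(all(diff(rates["far", ]) >= 0))
    expect_true(all(diff(rates["frr", ]) <= 0))
  }
})

test_that("accuracy/precision/recall match a hand-computed confusion matrix", {
  pol <- auth_policy("cosine", 0.25)
  # genuine: 3 accepted (TP), 2 rejected (FN); impostor: 1 accepted (FP),
  # 4 rejected (TN) -> acc 7/10, prec 3/4, rec 3/5
  trials <- list(genuine = c(0.1, 0.2, 0.25, 0.3, 0.4),
                 impostor = c(0.2, 0.3, 0.5, 0.6, 0.7))
  expect_equal(accuracy_precision_recall(trials, pol),
               c(accuracy = 0.7, precision = 0.75, recall = 0.6))
  # all rejected: recall 0, precision undefined (NA)
  none <- accuracy_precision_recall(list(genuine = c(1, 2), impostor = c(3)),
                                    auth_policy("cosine", 0.5))
  expect_equal(none[["recall"]], 0)
  expect_true(is.na(none[["precision"]]))
  # perfectly separated toy at its EER threshold
  eer <- eer_threshold(det_curve(toy_sep))
  expect_equal(accuracy_precision_recall(toy_sep,
                                         auth_policy("cosine", eer$threshold)),
               c(accuracy = 1, precision = 1, recall = 1))
})

# ---- trial construction against a real (tiny) fingerprinter --------------

local_trial_fixture <- function(n_subjects = 3L, n_probes = 2L,
                                clone_sessions = FALSE) {
  p <- tiny_params()
  cohort <- tiny_cohort(n_subjects = n_subjects, n_channels = 2L,
                        duration_s = 8, seed = 77)
  if (clone_sessions) {
    cohort <- lapply(cohort, function(r) {
      if (identical(r$session, 2L)) {
        r1 <- Filter(function(q) identical(q$subject_id, r$subject_id) &&
                       identical(q$session, 1L), cohort)[[1]]
        r$data <- r1$data
      }
      r
    })
  }
  model <- build_classifier(tiny_config(2, seed = 2), c(4, 32, 2))
  model$trained <- TRUE
  f <- split_fingerprint(model)
  ids <- sprintf("S%02d", seq_len(n_subjects))
  split <- cohort_split(ids[1:2], ids[-(1:2)])
  ts <- build_trials(cohort, f, cohort[[1]]$channel_names, p, split,
                     n_probes = n_probes, max_inputs = 10)
  list(ts = ts, split = split, n_subjects = n_subjects, n_probes = n_probes)
}

test_that("trial counts follow the s*p / s*(s-1)*p closed forms", {
  for (np in c(1L, 2L)) {
    fx <- local_trial_fixture(n_subjects = 3L, n_probes = np)
    tr <- fx$ts$trials
    s <- fx$n_subjects
    expect_identical(sum(tr$type == "genuine"), s * np)
    expect_identical(sum(tr$type == "impostor"), s * (s - 1L) * np)
    # brute-force enumeration: every (claimed, probe-subject, index) distinct
    expect_identical(nrow(unique(tr[, 1:3])), nrow(tr))
  }
})

test_that("probes identical to enrollments give zero genuine distances", {
  fx <- local_trial_fixture(n_probes = 1L, clone_sessions = TRUE)
  tr <- trial_distances(fx$ts, "cosine")
  expect_true(all(tr$distance[tr$type == "genuine"] < 1e-12))
  expect_true(all(tr$distance >= 0))
})

test_that("four-case matrix recounts per cell and pools to overall accuracy", {
  fx <- local_trial_fixture(n_subjects = 4L, n_probes = 2L)
  tr <- trial_distances(fx$ts, "cosine")
  pol <- auth_policy("cosine", stats::median(tr$distance))
  fc <- four_case_matrix(tr, pol)
  # brute-force per-cell recount
  for (g in c("alpha", "beta")) {
    for (ty in c("genuine", "impostor")) {
      d <- tr$distance[tr$group == g & tr$type == ty]
      want <- if (ty == "genuine") mean(d <= pol$threshold)
              else mean(d > pol$threshold)
      expect_equal(fc[g, ty], want)
    }
  }
  # weighted pooling equals the overall accuracy
  w <- table(tr$group, tr$type)[rownames(fc), colnames(fc)]
  overall <- accuracy_precision_recall(tr, pol)[["accuracy"]]
  expect_equal(sum(fc * w) / sum(w), overall)

  # threshold 0: impostor cells perfect, genuine cells are the zero fraction
  fc0 <- four_case_matrix(tr, auth_policy("cosine", 0))
  expect_true(all(fc0[, "impostor"] == 1))

  # empty cells are NA, not zero
  tr_alpha <- tr[tr$group == "alpha", ]
  fcA <- four_case_matrix(tr_alpha, pol)
  expect_true(all(is.na(fcA["beta", ])))
})
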