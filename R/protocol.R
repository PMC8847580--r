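#' Train the identification model on a cohort
#'
#' Builds preprocessed inputs from the given recordings, performs a
#' leakage-safe per-recording block split, trains the convolutional
#' classifier on the training side and reports test identification accuracy.
#'
#' @param cohort list of [eeg_recording()]s (typically one training session
#'   per subject).
#' @param channels ordered channel set C.
#' @param params a [window_params()].
#' @param config a [classifier_config()] template (`n_classes` is replaced
#'   by the subject count of `cohort`).
#' @param seed master seed (weight init, shuffling, dropout, split).
#' @param epochs optional override.
#' @param max_inputs per-recording cap on augmented inputs (compute budget).
#' @param orthogonalize apply Gram-Schmidt in `channels` order.
#' @param train_frac fraction of each recording's inputs used for training.
#' @return list: `model` (trained `cnn_model`), `subjects` (label order),
#'   `test_accuracy`.
#' @export
train_cohort_model <- function(cohort, channels, params = window_params(),
                               config = NULL, seed = 1L, epochs = NULL,
                               max_inputs = NULL, orthogonalize = TRUE,
                               train_frac = 0.75) {
  subjects <- sort(unique(vapply(cohort, function(r) r$subject_id, character(1))))
  if (length(subjects) < 2L) stop("need at least two subjects", call. = FALSE)
  gam <- window_gamma(params)

  train_x <- list(); train_y <- integer(0)
  test_x <- list(); test_y <- integer(0)
  for (r in cohort) {
    inputs <- build_inputs(r, channels, params, orthogonalize = orthogonalize,
                           max_inputs = max_inputs)
    lab <- match(r$subject_id, subjects) - 1L
    n_i <- length(inputs)
    n_train <- max(1L, floor(train_frac * n_i))
    offs <- vapply(inputs, function(x) attr(x, "offset"), numeric(1))
    te <- which(offs >= offs[n_train] + gam)
    train_x <- c(train_x, inputs[seq_len(n_train)])
    train_y <- c(train_y, rep(lab, n_train))
    test_x <- c(test_x, inputs[te])
    test_y <- c(test_y, rep(lab, length(te)))
  }

  cfg_args <- if (is.null(config)) list() else unclass(config)
  cfg_args$n_classes <- length(subjects)
  cfg_args$seed <- as.integer(seed)
  cfg_args$stride <- NULL
  cfg <- do.call(classifier_config, cfg_args)

  model <- build_classifier(cfg, dim(train_x[[1]]))
  model <- train_classifier(model, train_x, train_y, epochs = epochs)
  acc <- if (length(test_x) > 0) {
    probs <- predict(model, test_x)
    mean(max.col(t(probs), ties.method = "first") - 1L == test_y)
  } else NA_real_

  list(model = model, subjects = subjects, test_accuracy = acc)
}

#' Run the full open-set authentication protocol on a cohort
#'
#' The complete pipeline: split subjects into Alpha (training) and Beta
#' (never seen); train the identification model on Alpha first-session
#' recordings; extract the fingerprinting function; enroll every subject
#' from session 1; build genuine/impostor trials against session-2 probes;
#' calibrate the per-distance threshold at the equal-error-rate point of the
#' DET curve computed on Alpha trials only; evaluate accuracy, precision,
#' recall and the {Alpha, Beta} x {genuine, impostor} four-case matrix on
#' all trials.
#'
#' @param cohort list of [eeg_recording()]s with two sessions per subject.
#' @param channels ordered channel set (default: all channels of the first
#'   recording).
#' @param params a [window_params()].
#' @param config a [classifier_config()] template.
#' @param n_alpha number of Alpha (training) subjects; defaults to
#'   `round(0.826 * n_subjects)`, mirroring a 90-of-109 split. Alpha users
#'   are the first `n_alpha` subjects in id order.
#' @param distances distance measures to calibrate and report.
#' @param n_probes probe segments per subject cut from session 2.
#' @param seed master seed.
#' @param epochs optional training-epoch override (desk-scale profile).
#' @param max_inputs per-recording input cap for training (desk-scale
#'   profile).
#' @param max_inputs_fp per-fingerprint cap on aggregated windows; defaults
#'   to `max_inputs`. Mean aggregation stabilizes quickly, so enrollment
#'   and probe fingerprints tolerate heavier thinning than training.
#' @param orthogonalize apply Gram-Schmidt preprocessing.
#' @return list: `split`, `subjects`, `identification_accuracy`, `model`,
#'   `fingerprinter`, `trial_set`, and per-distance `results` (threshold,
#'   EER, FAR/FRR at threshold, accuracy/precision/recall, four-case
#'   matrix).
#' @export
run_full_protocol <- function(cohort, channels = NULL,
                              params = window_params(), config = NULL,
                              n_alpha = NULL,
                              distances = c("cosine", "euclidean", "manhattan"),
                              n_probes = 4L, seed = 1L, epochs = NULL,
                              max_inputs = NULL, max_inputs_fp = max_inputs,
                              orthogonalize = TRUE) {
  subjects <- sort(unique(vapply(cohort, function(r) r$subject_id, character(1))))
  if (is.null(n_alpha)) n_alpha <- round(90 / 109 * length(subjects))
  n_alpha <- as.integer(n_alpha)
  if (n_alpha < 2L || n_alpha > length(subjects)) {
    stop("n_alpha must be in [2, n_subjects]", call. = FALSE)
  }
  split <- cohort_split(alpha_ids = subjects[seq_len(n_alpha)],
                        beta_ids = setdiff(subjects, subjects[seq_len(n_alpha)]))
  if (is.null(channels)) channels <- cohort[[1]]$channel_names

  train_recs <- Filter(function(r) r$subject_id %in% split$alpha_ids &&
                         identical(r$session, 1L), cohort)
  fit <- train_cohort_model(train_recs, channels, params, config, seed = seed,
                            epochs = epochs, max_inputs = max_inputs,
                            orthogonalize = orthogonalize)
  f <- split_fingerprint(fit$model)

  ts <- build_trials(cohort, f, channels, params, split, n_probes = n_probes,
                     max_inputs = max_inputs_fp)

  results <- list()
  for (m in distances) {
    tr <- trial_distances(ts, m)
    # calibration must not see Beta subjects at all: Alpha-claimed trials
    # with Alpha-sourced probes only
    alpha_tr <- tr[tr$group == "alpha" &
                     tr$probe_subject %in% split$alpha_ids, ]
    curve <- det_curve(alpha_tr)
    eer <- eer_threshold(curve)
    policy <- auth_policy(m, eer$threshold)
    results[[m]] <- list(
      distance = m,
      threshold = eer$threshold,
      eer = eer$eer,
      far_alpha = eer$far, frr_alpha = eer$frr,
      metrics = accuracy_precision_recall(tr, policy),
      four_case = four_case_matrix(tr, policy),
      det = curve)
  }

  list(split = split, subjects = subjects,
       identification_accuracy = fit$test_accuracy,
       model = fit$model, fingerprinter = f, trial_set = ts,
       results = results)
}
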