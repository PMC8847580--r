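#' Classification accuracy of a channel set
#'
#' The scorer consumed by the orthogonal forward search: builds model inputs
#' from the cohort restricted to `channels` (with sequential Gram-Schmidt in
#' list order when `orthogonalize = TRUE`), performs a seeded per-recording
#' train/test split, trains the convolutional identification model from
#' scratch and returns its test accuracy.
#'
#' The default split is *contiguous-block*: the first `train_frac` of each
#' recording's inputs train the model and testing uses only inputs whose
#' sampling windows start at least `Gamma` samples after the last training
#' window, so no raw sample is shared between the two sides. A
#' `split = "random"` mode reproduces a plain random split over overlapping
#' windows (which permits temporal leakage; see the vignette).
#'
#' Degeneracy guard: a candidate channel whose orthogonalized residual is
#' numerically zero (relative norm below `1e-8`, e.g. an exact duplicate of
#' an already-selected channel) carries no signal; the scorer refuses it
#' with an error, which the forward search treats as a skipped candidate.
#'
#' @param cohort list of [eeg_recording()]s (>= 2 subjects).
#' @param channels ordered channel labels to evaluate.
#' @param params a [window_params()].
#' @param config a [classifier_config()] template; its `n_classes` is
#'   replaced by the cohort's subject count. `NULL` uses defaults.
#' @param split_seed seed for the split and for training.
#' @param orthogonalize apply Gram-Schmidt in `channels` order.
#' @param split `"block"` (leakage-safe, default) or `"random"`.
#' @param train_frac fraction of inputs used for training.
#' @param epochs optional override of `config$epochs`.
#' @param max_inputs per-recording cap on augmented inputs.
#' @return accuracy fraction in `[0, 1]`.
#' @export
score_channel_set <- function(cohort, channels, params = window_params(),
                              config = NULL, split_seed = 1L,
                              orthogonalize = TRUE,
                              split = c("block", "random"),
                              train_frac = 0.75, epochs = NULL,
                              max_inputs = NULL) {
  split <- match.arg(split)
  subjects <- sort(unique(vapply(cohort, function(r) r$subject_id, character(1))))
  if (length(subjects) < 2L) {
    stop("scorer error: cohort must contain at least two subjects", call. = FALSE)
  }

  # degeneracy guard on orthogonalized residuals
  if (orthogonalize && length(channels) > 1L) {
    for (r in cohort) {
      sig <- preprocess_channels(r, channels, ortho = TRUE)
      last <- sig[[length(channels)]]
      ref <- minmax_normalize(channel_signal(r, channels[length(channels)]))
      if (sqrt(sum(last^2)) < 1e-8 * sqrt(sum(ref^2))) {
        stop(sprintf(
          "degenerate channel set: '%s' has numerically zero residual after orthogonalization",
          channels[length(channels)]), call. = FALSE)
      }
    }
  }

  gam <- window_gamma(params)
  train_x <- list(); train_y <- integer(0)
  test_x <- list(); test_y <- integer(0)
  with_local_seed(split_seed, {
    for (r in cohort) {
      inputs <- build_inputs(r, channels, params,
                             orthogonalize = orthogonalize,
                             max_inputs = max_inputs)
      lab <- match(r$subject_id, subjects) - 1L
      n_i <- length(inputs)
      n_train <- max(1L, floor(train_frac * n_i))
      if (split == "random") {
        tr <- sample.int(n_i, n_train)
        te <- setdiff(seq_len(n_i), tr)
      } else {
        offs <- vapply(inputs, function(x) attr(x, "offset"), numeric(1))
        tr <- seq_len(n_train)
        last_train_end <- offs[n_train] + gam
        te <- which(offs >= last_train_end)
      }
      if (length(te) == 0L) {
        stop("scorer error: no test inputs after the block split gap", call. = FALSE)
      }
      train_x <- c(train_x, inputs[tr]); train_y <- c(train_y, rep(lab, length(tr)))
      test_x <- c(test_x, inputs[te]);  test_y <- c(test_y, rep(lab, length(te)))
    }
  })

  cfg_args <- if (is.null(config)) list() else unclass(config)
  cfg_args$n_classes <- length(subjects)
  cfg_args$seed <- as.integer(split_seed)
  cfg_args$stride <- NULL
  cfg <- do.call(classifier_config, cfg_args)

  shape <- dim(train_x[[1]])
  model <- build_classifier(cfg, shape)
  model <- train_classifier(model, train_x, train_y, epochs = epochs)

  probs <- predict(model, test_x)
  pred <- max.col(t(probs), ties.method = "first") - 1L
  mean(pred == test_y)
}

#' Orthogonal greedy forward channel selection
#'
#' Starts from an empty selected set C and the search space E; at each of
#' `max_channels` steps every remaining candidate is scored on `C + {c}`
#' (with within-recording Gram-Schmidt applied in selection order when
#' `orthogonalize = TRUE`) and the arg-max candidate is appended. Ties are
#' broken toward the candidate earliest in the sorted label order, for
#' determinism. A candidate on which the scorer fails is skipped with a
#' warning; a step where every candidate fails raises a selection error. An
#' optional plateau rule stops early when the step-to-step accuracy gain
#' falls below `plateau_eps`.
#'
#' @param cohort list of [eeg_recording()]s with subject ids.
#' @param search_space character vector E of candidate labels, or
#'   `"commercial20"` for the built-in commercial montage subset.
#' @param max_channels number of channels to select (k <= |E|).
#' @param params,config,orthogonalize,seed passed to the scorer.
#' @param scorer scoring function with the signature of
#'   [score_channel_set()]; must be deterministic given the seed.
#' @param plateau_eps optional minimum accuracy gain to continue.
#' @param ... further arguments passed to the scorer (e.g. `epochs`,
#'   `max_inputs`).
#' @return An object of class `selection_result`: `selected` (ordered
#'   labels), `search_space_remaining`, `step_scores`, and an `audit` list
#'   of per-step candidate scores.
#' @export
forward_select <- function(cohort, search_space, max_channels,
                           params = window_params(), config = NULL,
                           orthogonalize = TRUE, seed = 1L,
                           scorer = score_channel_set, plateau_eps = NULL,
                           ...) {
  if (identical(search_space, "commercial20")) search_space <- montage_commercial()
  E <- sort(unique(as.character(search_space)))
  max_channels <- as.integer(max_channels)
  if (max_channels > length(E)) {
    stop("max_channels exceeds the search space size", call. = FALSE)
  }
  selected <- character(0)
  step_scores <- numeric(0)
  audit <- list()

  while (length(selected) < max_channels) {
    candidates <- sort(setdiff(E, selected))
    scores <- rep(NA_real_, length(candidates))
    names(scores) <- candidates
    for (j in seq_along(candidates)) {
      scores[j] <- tryCatch(
        scorer(cohort, c(selected, candidates[j]), params = params,
               config = config, split_seed = seed,
               orthogonalize = orthogonalize, ...),
        error = function(e) {
          warning(sprintf("candidate '%s' skipped at step %d: %s",
                          candidates[j], length(selected) + 1L,
                          conditionMessage(e)), call. = FALSE)
          NA_real_
        })
    }
    if (all(is.na(scores))) {
      stop("selection error: every candidate failed at step ",
           length(selected) + 1L, call. = FALSE)
    }
    best <- which.max(scores)            # first max in sorted order
    if (!is.null(plateau_eps) && length(step_scores) > 0L &&
        scores[best] - step_scores[length(step_scores)] < plateau_eps) {
      break
    }
    selected <- c(selected, candidates[best])
    step_scores <- c(step_scores, unname(scores[best]))
    audit[[length(audit) + 1L]] <- scores
  }

  structure(list(selected = selected,
                 search_space_remaining = setdiff(E, selected),
                 step_scores = step_scores, audit = audit,
                 orthogonalized = orthogonalize),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", if (x$orthogonalized) "(orthogonalized)" else "", "\n")
  if (length(x$selected) == 0L) {
    cat("  (empty selection)\n")
  } else {
    for (i in seq_along(x$selected)) {
      cat(sprintf("  step %d: %-4s accuracy %.4f\n", i, x$selected[i],
                  x$step_scores[i]))
    }
  }
  invisible(x)
}
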