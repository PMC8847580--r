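#' Alpha/Beta cohort split
#'
#' `alpha_ids` are the subjects available when the identification model is
#' trained; `beta_ids` are never-seen subjects used to probe open-set
#' universality. The two sets must be disjoint.
#'
#' @param alpha_ids,beta_ids character vectors of subject ids.
#' @return An object of class `cohort_split`.
#' @export
cohort_split <- function(alpha_ids, beta_ids) {
  alpha_ids <- as.character(alpha_ids); beta_ids <- as.character(beta_ids)
  if (length(intersect(alpha_ids, beta_ids)) > 0L) {
    stop("alpha and beta subject sets must be disjoint", call. = FALSE)
  }
  structure(list(alpha_ids = alpha_ids, beta_ids = beta_ids),
            class = "cohort_split")
}

#' Build genuine and impostor verification trials
#'
#' Enrollment fingerprints come from each subject's first-session recording;
#' probe fingerprints come from contiguous segments of a disjoint session
#' (honest stand-in for re-recording under the same conditions). Genuine
#' trials compare a subject's enrollment with their own probes; impostor
#' trials compare an enrollment with every other subject's probes. Each
#' trial is labelled with the claimed (enrolled) identity's Alpha/Beta
#' membership. For `s` subjects with `p` probes each this yields `s * p`
#' genuine and `s * (s - 1) * p` impostor trials.
#'
#' @param cohort list of [eeg_recording()]s; each subject needs a recording
#'   with `session == enroll_session` and one with `session ==
#'   probe_session`. Subjects missing either are excluded with a warning.
#' @param f an `eeg_fingerprinter`.
#' @param channels ordered channel set C.
#' @param params a [window_params()].
#' @param split a [cohort_split()] labelling subjects Alpha/Beta.
#' @param n_probes number of contiguous probe segments cut from the probe
#'   session (each must still span at least Gamma samples).
#' @param enroll_session,probe_session session identifiers.
#' @param max_inputs per-fingerprint cap on augmented windows (compute
#'   budget control; `NULL` = all).
#' @return An object of class `trial_set` holding enrollment and probe
#'   fingerprints plus a per-trial provenance table; distances under a given
#'   measure are computed with [trial_distances()].
#' @export
build_trials <- function(cohort, f, channels, params = window_params(),
                         split, n_probes = 4L, enroll_session = 1L,
                         probe_session = 2L, max_inputs = NULL) {
  stopifnot(inherits(split, "cohort_split"))
  gam <- window_gamma(params)
  subjects <- unique(vapply(cohort, function(r) r$subject_id, character(1)))
  find_rec <- function(id, session) {
    for (r in cohort) {
      if (identical(r$subject_id, id) && identical(r$session, session)) return(r)
    }
    NULL
  }

  enr <- list(); probes <- list(); groups <- character(0)
  for (id in subjects) {
    re <- find_rec(id, enroll_session)
    rp <- find_rec(id, probe_session)
    if (is.null(re) || is.null(rp)) {
      warning(sprintf("subject '%s' lacks disjoint enrollment/probe sessions; excluded",
                      id))
      next
    }
    seg_len <- ncol(rp$data) %/% n_probes
    if (seg_len < gam) {
      stop(sprintf("probe segments of subject '%s' are shorter than Gamma", id),
           call. = FALSE)
    }
    enr[[id]] <- as.numeric(
      fingerprint_sample(f, re, channels, params, max_inputs = max_inputs))
    probes[[id]] <- lapply(seq_len(n_probes), function(k) {
      seg <- rp$data[, ((k - 1) * seg_len + 1):(k * seg_len), drop = FALSE]
      rec <- eeg_recording(seg, rp$sample_rate_hz, rp$channel_names,
                           subject_id = id, session = probe_session)
      as.numeric(fingerprint_sample(f, rec, channels, params,
                                    max_inputs = max_inputs))
    })
    groups[id] <- if (id %in% split$alpha_ids) "alpha"
                  else if (id %in% split$beta_ids) "beta" else "unsplit"
  }
  ids <- names(enr)
  if (length(ids) < 2L) stop("need at least two usable subjects", call. = FALSE)

  rows <- list()
  for (claimed in ids) {
    for (src in ids) {
      for (k in seq_len(n_probes)) {
        rows[[length(rows) + 1L]] <- data.frame(
          claimed = claimed, probe_subject = src, probe_index = k,
          type = if (claimed == src) "genuine" else "impostor",
          group = groups[claimed], stringsAsFactors = FALSE)
      }
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  structure(list(trials = trials, enrollments = enr, probes = probes),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  tab <- table(x$trials$type, x$trials$group)
  cat("<trial_set>\n"); print(tab); invisible(x)
}

#' Distances of every trial under one measure
#'
#' @param ts a [build_trials()] result.
#' @param method distance name.
#' @return the trial provenance data frame with a `distance` column added.
#' @export
trial_distances <- function(ts, method = "cosine") {
  stopifnot(inherits(ts, "trial_set"))
  tr <- ts$trials
  tr$distance <- vapply(seq_len(nrow(tr)), function(i) {
    fingerprint_distance(ts$enrollments[[tr$claimed[i]]],
                         ts$probes[[tr$probe_subject[i]]][[tr$probe_index[i]]],
                         method)
  }, numeric(1))
  tr
}

# accept a trial_distances() data frame or a list(genuine=, impostor=)
as_distance_lists <- function(trials) {
  if (is.data.frame(trials)) {
    list(genuine = trials$distance[trials$type == "genuine"],
         impostor = trials$distance[trials$type == "impostor"])
  } else if (is.list(trials) &&
             all(c("genuine", "impostor") %in% names(trials))) {
    list(genuine = as.numeric(trials$genuine),
         impostor = as.numeric(trials$impostor))
  } else {
    stop("trials must be a trial-distance data frame or a list with genuine/impostor distances",
         call. = FALSE)
  }
}

#' False acceptance and false rejection rates at a threshold
#'
#' `FAR = #(impostor distances <= threshold) / #impostor` (Type I error),
#' `FRR = #(genuine distances > threshold) / #genuine` (Type II error).
#' Acceptance is `<=` (the boundary accepts).
#'
#' @param trials a [trial_distances()] data frame, or a list with `genuine`
#'   and `impostor` distance vectors.
#' @param threshold decision threshold.
#' @return named numeric vector `c(far = ..., frr = ...)`.
#' @export
far_frr <- function(trials, threshold) {
  d <- as_distance_lists(trials)
  if (length(d$genuine) == 0L || length(d$impostor) == 0L) {
    stop("undefined rate: both genuine and impostor trials are required",
         call. = FALSE)
  }
  c(far = mean(d$impostor <= threshold),
    frr = mean(d$genuine > threshold))
}

#' Detection error trade-off curve
#'
#' FAR and FRR swept over a threshold grid. The default grid is the set of
#' midpoints between consecutive sorted pooled distances, plus points below
#' the minimum and above the maximum, which covers every achievable
#' (FAR, FRR) pair exactly.
#'
#' @param trials as in [far_frr()].
#' @param thresholds optional explicit threshold grid.
#' @return An object of class `det_curve`: data frame with `threshold`,
#'   `far`, `frr`, ordered by increasing threshold.
#' @export
det_curve <- function(trials, thresholds = NULL) {
  d <- as_distance_lists(trials)
  if (is.null(thresholds)) {
    pooled <- sort(unique(c(d$genuine, d$impostor)))
    if (length(pooled) == 1L) {
      thresholds <- c(pooled - 1, pooled, pooled + 1)
    } else {
      mids <- (pooled[-1] + pooled[-length(pooled)]) / 2
      step <- min(diff(pooled))
      thresholds <- c(pooled[1] - step / 2, pooled, mids,
                      pooled[length(pooled)] + step / 2)
    }
    thresholds <- sort(unique(thresholds))
  }
  if (length(thresholds) == 0L) stop("threshold grid is empty", call. = FALSE)
  thresholds <- sort(thresholds)
  rates <- vapply(thresholds, function(t) far_frr(d, t), numeric(2))
  out <- data.frame(threshold = thresholds, far = rates["far", ],
                    frr = rates["frr", ])
  class(out) <- c("det_curve", class(out))
  out
}

#' Equal-error-rate operating point
#'
#' The grid point minimizing `|FAR - FRR|` (ties broken toward the lower
#' threshold); the reported EER is the mean of FAR and FRR there.
#'
#' @param curve a [det_curve()].
#' @return list with `threshold`, `eer`, `far`, `frr`.
#' @export
eer_threshold <- function(curve) {
  stopifnot(inherits(curve, "det_curve"), nrow(curve) > 0)
  gap <- abs(curve$far - curve$frr)
  i <- which(gap == min(gap))[1]      # curve is threshold-ordered
  list(threshold = curve$threshold[i],
       eer = (curve$far[i] + curve$frr[i]) / 2,
       far = curve$far[i], frr = curve$frr[i])
}

#' Four-case accuracy matrix: {Alpha, Beta} x {genuine, impostor}
#'
#' Per-cell fraction of correct decisions under the policy (genuine
#' accepted, impostor rejected). Empty cells are reported as `NA` (absent),
#' not zero.
#'
#' @param trials a [trial_distances()] data frame with `group` provenance.
#' @param policy an [auth_policy()] (its `method` must match the measure the
#'   distances were computed with).
#' @return 2x2 numeric matrix, rows `alpha`/`beta`, columns
#'   `genuine`/`impostor`.
#' @export
four_case_matrix <- function(trials, policy) {
  stopifnot(is.data.frame(trials), inherits(policy, "auth_policy"))
  out <- matrix(NA_real_, 2, 2,
                dimnames = list(c("alpha", "beta"), c("genuine", "impostor")))
  for (g in rownames(out)) {
    for (ty in colnames(out)) {
      d <- trials$distance[trials$group == g & trials$type == ty]
      if (length(d) == 0L) next
      acc <- d <= policy$threshold
      out[g, ty] <- if (ty == "genuine") mean(acc) else mean(!acc)
    }
  }
  out
}

#' Overall accuracy, precision and recall under a policy
#'
#' Genuine-accept is the positive class: `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`; accuracy is over all trials. Undefined ratios
#' (zero denominators) are reported as `NA`.
#'
#' @param trials as in [far_frr()].
#' @param policy an [auth_policy()].
#' @return named numeric vector `c(accuracy, precision, recall)`.
#' @export
accuracy_precision_recall <- function(trials, policy) {
  stopifnot(inherits(policy, "auth_policy"))
  d <- as_distance_lists(trials)
  tp <- sum(d$genuine <= policy$threshold)
  fn <- sum(d$genuine > policy$threshold)
  fp <- sum(d$impostor <= policy$threshold)
  tn <- sum(d$impostor > policy$threshold)
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}
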