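#' Distances between fingerprint vectors
#'
#' Euclidean (`||A - B||_2`), Manhattan (`||A - B||_1`) and cosine distance.
#' Note on the cosine measure: the quantity conventionally printed as
#' "cosine distance" in biometric work is algebraically cosine *similarity*
#' (large when vectors align). Since verification accepts when
#' `distance <= threshold`, this package implements cosine distance as
#' `1 - similarity`, so that small values mean similar for all three
#' measures and the accept-if-below rule points the same way everywhere.
#'
#' @param a,b numeric vectors of equal length (for cosine, both non-zero).
#' @param method one of `"euclidean"`, `"manhattan"`, `"cosine"`.
#' @return single non-negative number; 0 for identical inputs (cosine: 0 for
#'   positively parallel inputs).
#' @export
fingerprint_distance <- function(a, b,
                                 method = c("cosine", "euclidean", "manhattan")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("shape error: fingerprint vectors differ in length", call. = FALSE)
  }
  switch(method,
    euclidean = sqrt(sum((a - b)^2)),
    manhattan = sum(abs(a - b)),
    cosine = {
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) {
        stop("undefined distance: cosine distance of a zero vector",
             call. = FALSE)
      }
      d <- 1 - sum(a * b) / (na * nb)
      max(d, 0)   # clamp tiny negative round-off
    })
}

#' Verification policy
#'
#' @param method distance name (see [fingerprint_distance()]).
#' @param threshold non-negative acceptance threshold; a claim is accepted
#'   when the measured distance is `<= threshold` (boundary accepts).
#' @return An object of class `auth_policy`.
#' @export
auth_policy <- function(method = "cosine", threshold) {
  method <- match.arg(method, c("cosine", "euclidean", "manhattan"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  structure(list(method = method, threshold = as.numeric(threshold)),
            class = "auth_policy")
}

#' Enrollment store: identities mapped to fingerprints only
#'
#' The privacy contract of the system: the store holds, per identity, one
#' fixed-length fingerprint vector plus enrollment metadata (channel list,
#' window-parameter echo, model version) — never raw signal arrays and never
#' model inputs. Serialization ([save_store()]/[load_store()]) preserves
#' exactly that.
#'
#' @param f the `eeg_fingerprinter` the store is bound to.
#' @param channels ordered channel set used at enrollment.
#' @param params the [window_params()] used at enrollment.
#' @return An object of class `enrollment_store`.
#' @export
enrollment_store <- function(f, channels, params = window_params()) {
  stopifnot(inherits(f, "eeg_fingerprinter"))
  structure(list(format_version = 1L,
                 model_version = f$model_version,
                 fingerprint_len = f$fingerprint_len,
                 channels = as.character(channels),
                 params = unclass(params)[c("T", "delta", "eta", "Delta")],
                 identities = list()),
            class = "enrollment_store")
}

#' @export
print.enrollment_store <- function(x, ...) {
  cat(sprintf("<enrollment_store> %d identities | m=%d | model %s\n",
              length(x$identities), x$fingerprint_len, x$model_version))
  invisible(x)
}

#' Enroll an identity
#'
#' Computes the fingerprint of the enrollment recording server-side and
#' stores it under `identity`. The raw recording is not retained.
#'
#' @param store an [enrollment_store()].
#' @param identity identity string.
#' @param rec enrollment [eeg_recording()].
#' @param f the `eeg_fingerprinter` (must match the store's model version).
#' @param overwrite replace an existing enrollment.
#' @param ... passed to [fingerprint_sample()] (e.g. `max_inputs`).
#' @return the updated store.
#' @export
enroll <- function(store, identity, rec, f, overwrite = FALSE, ...) {
  stopifnot(inherits(store, "enrollment_store"))
  identity <- as.character(identity)
  if (!identical(f$model_version, store$model_version)) {
    stop("stale model: fingerprinter version does not match the store",
         call. = FALSE)
  }
  if (!overwrite && identity %in% names(store$identities)) {
    stop(sprintf("conflict: identity '%s' is already enrolled", identity),
         call. = FALSE)
  }
  params <- do.call(window_params, store$params)
  s <- fingerprint_sample(f, rec, store$channels, params, ...)
  store$identities[[identity]] <- as.numeric(s)
  store
}

#' Verify a claimed identity against the store
#'
#' Recomputes the fingerprint of the presented recording server-side and
#' accepts iff its distance to the stored fingerprint is `<= threshold`.
#' Unknown identities are rejected without a distance computation (a
#' distinct rejection reason, not a distance rejection).
#'
#' @param store an [enrollment_store()].
#' @param claimed_identity the claimed identity string.
#' @param rec probe [eeg_recording()].
#' @param f the `eeg_fingerprinter`.
#' @param policy an [auth_policy()].
#' @param ... passed to [fingerprint_sample()].
#' @return An `auth_decision`: list with `accepted`, `distance`, `policy`,
#'   `reason`.
#' @export
verify <- function(store, claimed_identity, rec, f, policy, ...) {
  stopifnot(inherits(store, "enrollment_store"), inherits(policy, "auth_policy"))
  claimed_identity <- as.character(claimed_identity)
  if (!identical(f$model_version, store$model_version)) {
    stop("stale model: fingerprinter version does not match the store",
         call. = FALSE)
  }
  if (!(claimed_identity %in% names(store$identities))) {
    return(structure(list(accepted = FALSE, distance = NA_real_,
                          policy = policy, reason = "unknown-identity"),
                     class = "auth_decision"))
  }
  params <- do.call(window_params, store$params)
  probe <- fingerprint_sample(f, rec, store$channels, params, ...)
  d <- fingerprint_distance(store$identities[[claimed_identity]], probe,
                            policy$method)
  structure(list(accepted = d <= policy$threshold, distance = d,
                 policy = policy, reason = "distance"),
            class = "auth_decision")
}

#' @export
print.auth_decision <- function(x, ...) {
  cat(sprintf("<auth_decision> %s  (%s distance %s, threshold %g)\n",
              if (x$accepted) "ACCEPTED" else "REJECTED",
              x$policy$method,
              if (is.na(x$distance)) x$reason else formatC(x$distance),
              x$policy$threshold))
  invisible(x)
}

#' Serialize / load an enrollment store
#'
#' JSON container with a versioned header. Saving validates the privacy
#' contract: every stored object must be a plain numeric vector of the
#' store's fingerprint length — no matrices, no higher-dimensional arrays,
#' nothing with raw-recording dimensions.
#'
#' @param store an [enrollment_store()].
#' @param path file path.
#' @return `save_store()` returns `path` invisibly; `load_store()` returns
#'   the store.
#' @export
save_store <- function(store, path) {
  stopifnot(inherits(store, "enrollment_store"))
  for (id in names(store$identities)) {
    v <- store$identities[[id]]
    if (!is.numeric(v) || !is.null(dim(v)) ||
        length(v) != store$fingerprint_len) {
      stop(sprintf(
        "privacy contract violation: entry '%s' is not a plain length-%d fingerprint",
        id, store$fingerprint_len), call. = FALSE)
    }
  }
  payload <- list(container = "brainprint-enrollment-store",
                  format_version = store$format_version,
                  model_version = store$model_version,
                  fingerprint_len = store$fingerprint_len,
                  channels = store$channels,
                  params = store$params,
                  identities = lapply(store$identities, as.numeric))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$container, "brainprint-enrollment-store")) {
    stop("format error: not an enrollment store", call. = FALSE)
  }
  ids <- p$identities
  if (is.null(ids)) ids <- list() else ids <- lapply(ids, as.numeric)
  structure(list(format_version = as.integer(p$format_version),
                 model_version = p$model_version,
                 fingerprint_len = as.integer(p$fingerprint_len),
                 channels = as.character(p$channels),
                 params = lapply(p$params, as.integer),
                 identities = ids),
            class = "enrollment_store")
}
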