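#' Canonical double-gamma HRF
#'
#' The standard hemodynamic response: a gamma density peaking near 6 s
#' minus an undershoot gamma peaking near 16 s at 1/6 amplitude, scaled so
#' the peak response is 1.
#'
#' @param t Time in seconds (vector); the response is 0 for `t < 0`.
#' @param peak,undershoot Gamma shape parameters (rate 1) for response and
#'   undershoot.
#' @param ratio Response/undershoot amplitude ratio.
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  raw <- function(x) stats::dgamma(x, peak, 1) - stats::dgamma(x, undershoot, 1) / ratio
  key <- paste(peak, undershoot, ratio)
  scale <- .hrf_scale_cache[[key]]
  if (is.null(scale)) {
    grid <- seq(0, peak + undershoot, by = 0.01)
    scale <- max(raw(grid))
    assign(key, scale, envir = .hrf_scale_cache)
  }
  out <- numeric(length(t))
  ok <- t >= 0
  out[ok] <- raw(t[ok]) / scale
  out
}

.hrf_scale_cache <- new.env(parent = emptyenv())

#' Discrete cosine drift basis
#'
#' DCT regressors equivalent to a high-pass filter with the given cutoff
#' period (default 128 s), excluding the constant term.
#'
#' @param n_scans Number of scans.
#' @param tr Repetition time in seconds.
#' @param cutoff High-pass cutoff period in seconds.
#' @return Matrix `n_scans x K` (possibly 0 columns) of unit-norm cosines.
#' @export
dct_basis <- function(n_scans, tr, cutoff = 128) {
  K <- floor(2 * n_scans * tr / cutoff)
  t <- seq_len(n_scans) - 1L
  if (K < 1L) return(matrix(numeric(0), n_scans, 0))
  B <- vapply(seq_len(K), function(k)
    sqrt(2 / n_scans) * cos(pi * (2 * t + 1) * k / (2 * n_scans)),
    numeric(n_scans))
  colnames(B) <- paste0("drift", seq_len(K))
  B
}

# Regressor labels for the 8 events of interest, in canonical order.
EVENT_TYPES <- c("dw1_match", "cw_match", "dw2_match",
                 "dw1_mismatch", "cw_mismatch", "dw2_mismatch",
                 "resp_match", "resp_mismatch")

# Convolved event regressors sampled at scan times: each event contributes
# the HRF evaluated at (t - onset); events are modeled as impulses.
event_regressors <- function(schedule, scan_times, types = EVENT_TYPES) {
  X <- matrix(0, length(scan_times), length(types),
              dimnames = list(NULL, types))
  for (j in seq_along(types)) {
    onsets <- schedule$onset[schedule$trial_type == types[j]]
    for (o in onsets) X[, j] <- X[, j] + canonical_hrf(scan_times - o)
  }
  X[, colSums(abs(X)) > 0, drop = FALSE]
}

#' Build an event-related GLM design matrix
#'
#' Columns: HRF-convolved indicators for the 8 events of interest (DW1, CW,
#' DW2 by match/mismatch plus the two response regressors; event types
#' absent from the schedule are dropped), nuisance series (e.g. the six
#' motion parameters), a DCT drift basis implementing the 128 s high-pass,
#' and an intercept.
#'
#' @param schedule An `event_schedule`.
#' @param nuisance Optional matrix of nuisance regressors (`n_scans` rows).
#' @param tr Repetition time; defaults to the schedule's.
#' @param n_scans Number of scans; defaults to the schedule's.
#' @param hp_cutoff High-pass cutoff in seconds (default 128).
#' @return A `design_matrix`: numeric matrix with unique column names and
#'   attributes `event_cols` (names of the event regressors) and `tr`.
#' @export
build_design <- function(schedule, nuisance = NULL, tr = NULL, n_scans = NULL,
                         hp_cutoff = 128) {
  if (is.null(tr)) tr <- attr(schedule, "tr")
  if (is.null(n_scans)) n_scans <- attr(schedule, "n_scans")
  stopifnot(is.numeric(tr), tr > 0, n_scans >= 1)
  if (anyDuplicated(paste(schedule$onset, schedule$trial_type)))
    stop("duplicate event (same onset and type) in schedule")
  scan_times <- (seq_len(n_scans) - 1L) * tr
  Xe <- event_regressors(schedule, scan_times)
  parts <- list(Xe)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_scans) stop("nuisance rows must equal scan count")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    parts <- c(parts, list(nuisance))
  }
  parts <- c(parts, list(dct_basis(n_scans, tr, hp_cutoff),
                         intercept = matrix(1, n_scans, 1,
                                            dimnames = list(NULL, "intercept"))))
  X <- do.call(cbind, parts)
  if (anyDuplicated(colnames(X))) stop("design column names must be unique")
  structure(X, class = c("design_matrix", "matrix"),
            event_cols = colnames(Xe), tr = tr)
}
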