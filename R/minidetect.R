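## Template-matching detection of miniature synaptic events
## (Clements & Bekkers sliding least-squares criterion).

#' Build a biexponential detection template
#'
#' Constructs the unit-peak kernel
#' \eqn{w(t) = (1 - e^{-t/\tau_r}) e^{-t/\tau_d}}, sampled at `dt` and
#' normalized so its maximum is exactly 1 (`w(0) = 0`).
#'
#' @param rise_tau,decay_tau rise and decay time constants (ms);
#'   `rise_tau < decay_tau` required.
#' @param length_ms template duration (ms); at least ~5 decay constants is
#'   recommended so the tail is negligible.
#' @param dt sampling interval (s).
#' @return an object of class `cb_template` with fields `kernel`, `dt`,
#'   `rise_tau`, `decay_tau`.
#' @export
build_template <- function(rise_tau, decay_tau, length_ms = 5 * decay_tau,
                           dt = 1e-4) {
  check_that(is_scalar_num(rise_tau) && rise_tau > 0, "rise_tau must be > 0")
  check_that(is_scalar_num(decay_tau) && decay_tau > rise_tau,
             "decay_tau must exceed rise_tau")
  check_that(is_scalar_num(length_ms) && length_ms > 0, "length_ms must be > 0")
  check_that(is_scalar_num(dt) && dt > 0, "dt must be > 0")
  structure(list(kernel = biexp_kernel(rise_tau, decay_tau, dt, length_ms),
                 dt = dt, rise_tau = rise_tau, decay_tau = decay_tau),
            class = "cb_template")
}

#' Detect miniature events by template matching
#'
#' Slides the template along the trace; at every lag the template is fitted
#' by least squares with a free scale and offset, and the detection
#' criterion is the fitted scale divided by the standard deviation of the
#' fit residuals (Clements-Bekkers). Local criterion maxima above
#' `threshold`, separated by at least `min_separation`, are reported as
#' events; the fitted scale is the event amplitude after polarity
#' normalization.
#'
#' Lags that would need samples beyond the end of the trace are skipped, so
#' no events are reported within one template length of the trace end.
#'
#' @param trace an `ephys_trace` (see [simulate_minis()]); its `polarity`
#'   field is used to rectify the signal before fitting.
#' @param template a [build_template()] object with matching `dt`.
#' @param threshold detection criterion threshold (criterion units,
#'   default 4).
#' @param min_separation minimum onset separation (ms); defaults to the
#'   template rise time + 2 ms.
#' @return an `event_table` data frame with columns `onset_s`, `amplitude`,
#'   `offset`, `criterion`, ordered by onset.
#' @export
cb_detect <- function(trace, template, threshold = 4,
                      min_separation = template$rise_tau + 2) {
  stopifnot(inherits(trace, "ephys_trace"), inherits(template, "cb_template"))
  check_that(isTRUE(all.equal(trace$dt, template$dt)),
             "trace and template must share dt")
  k <- template$kernel
  L <- length(k)
  x <- trace$polarity * trace$samples
  n <- length(x)
  check_that(n >= L, "trace shorter than template")
  crit <- cb_criterion(x, k)
  events <- pick_events(crit$criterion, threshold,
                        min_sep = max(1L, as.integer(round(
                          min_separation * 1e-3 / trace$dt))))
  out <- data.frame(onset_s = (events - 1) * trace$dt,
                    amplitude = crit$scale[events],
                    offset = trace$polarity * crit$offset[events],
                    criterion = crit$criterion[events])
  out <- out[out$amplitude > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

# Sliding least-squares fit of scale * kernel + offset at every lag.
# All rolling sums via stats::filter (exact, O(n L) in C).
cb_criterion <- function(x, k) {
  L <- length(k)
  n <- length(x)
  Sk <- sum(k); Skk <- sum(k * k)
  ones <- rep(1, L)
  ## filter(..., sides = 1)[t] = sum over window ending at t; the window
  ## starting at lag j ends at j + L - 1.
  ends <- L:n
  Sy <- stats::filter(x, ones, sides = 1)[ends]
  Syy <- stats::filter(x * x, ones, sides = 1)[ends]
  Sky <- stats::filter(x, rev(k), sides = 1)[ends]
  denom <- L * Skk - Sk^2
  scale <- (L * Sky - Sk * Sy) / denom
  offset <- (Sy - scale * Sk) / L
  sse <- Syy + scale^2 * Skk + L * offset^2 -
    2 * scale * Sky - 2 * offset * Sy + 2 * scale * offset * Sk
  se <- sqrt(pmax(sse, 0) / (L - 1))
  criterion <- ifelse(se > 0, scale / se, ifelse(scale > 0, Inf, -Inf))
  list(scale = scale, offset = offset, criterion = criterion)
}

# One event per contiguous suprathreshold excursion of the criterion (at
# the excursion's criterion peak), then thinned greedily by descending
# criterion so accepted events are >= min_sep samples apart. Taking one
# event per excursion keeps the slowly decaying criterion along an event's
# tail from spawning duplicates.
pick_events <- function(criterion, threshold, min_sep) {
  above <- criterion > threshold
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  cand <- vapply(runs, function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(criterion[seg])]
  }, integer(1))
  cand <- cand[order(criterion[cand], decreasing = TRUE)]
  taken <- integer(0)
  for (j in cand)
    if (length(taken) == 0L || min(abs(taken - j)) >= min_sep)
      taken <- c(taken, j)
  sort(taken)
}

#' Score a detection against ground truth
#'
#' Greedy one-to-one matching of detected to true events by nearest onset
#' time within `tolerance`.
#'
#' @param detected an `event_table` from [cb_detect()].
#' @param truth ground-truth data frame with `time_s` and `amplitude`
#'   (as returned by [simulate_minis()]).
#' @param tolerance maximum onset mismatch (ms).
#' @return a list with `sensitivity` (matched / true; `NA` if no true
#'   events), `fdr` (unmatched detected / detected; 1 if detections exist
#'   but truth is empty, `NA` if nothing was detected), `amplitude_bias`
#'   (mean relative amplitude error over matches) and `n_matched`.
#' @export
match_events <- function(detected, truth, tolerance = 1.5) {
  check_that(is_scalar_num(tolerance) && tolerance > 0,
             "tolerance must be > 0")
  td <- detected$onset_s
  tt <- truth$time_s
  tol_s <- tolerance * 1e-3
  if (length(tt) == 0L)
    return(list(sensitivity = NA_real_,
                fdr = if (length(td) > 0L) 1 else NA_real_,
                amplitude_bias = NA_real_, n_matched = 0L))
  if (length(td) == 0L)
    return(list(sensitivity = 0, fdr = NA_real_,
                amplitude_bias = NA_real_, n_matched = 0L))
  d <- abs(outer(td, tt, "-"))
  pairs <- which(d <= tol_s, arr.ind = TRUE)
  used_d <- logical(length(td)); used_t <- logical(length(tt))
  n_matched <- 0L
  rel_err <- numeric(0)
  if (nrow(pairs) > 0) {
    pairs <- pairs[order(d[pairs]), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (used_d[i] || used_t[j]) next
      used_d[i] <- used_t[j] <- TRUE
      n_matched <- n_matched + 1L
      rel_err <- c(rel_err,
                   (detected$amplitude[i] - truth$amplitude[j]) /
                     truth$amplitude[j])
    }
  }
  list(sensitivity = n_matched / length(tt),
       fdr = (length(td) - n_matched) / length(td),
       amplitude_bias = if (n_matched > 0) mean(rel_err) else NA_real_,
       n_matched = n_matched)
}
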