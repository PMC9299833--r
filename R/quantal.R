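## Quantal synaptic metrics: group mean minis, quantal content, PHP
## normalization, cumulative-EPSC RRP back-extrapolation, pr and PPR.

#' Group mean miniature amplitude
#'
#' The unweighted mean of per-NMJ mean mini amplitudes: every NMJ
#' contributes equally, regardless of how many events it supplied.
#'
#' @param values numeric vector of per-NMJ mean mini amplitudes.
#' @return scalar group mean.
#' @export
group_mean_mepsc <- function(values) {
  check_that(is.numeric(values) && length(values) >= 1 &&
               all(is.finite(values)), "need >= 1 finite per-NMJ mean")
  mean(values)
}

#' Per-NMJ quantal content
#'
#' Quantal content of each evoked-response NMJ is its mean evoked amplitude
#' divided by the group mean mini amplitude. Minis and evoked responses are
#' recorded from different NMJs, so the division deliberately crosses cells.
#'
#' @param epsc_means numeric vector of per-NMJ mean evoked amplitudes.
#' @param group_mepsc positive scalar group mean mini amplitude.
#' @return numeric vector of per-NMJ quantal contents.
#' @export
quantal_content <- function(epsc_means, group_mepsc) {
  check_that(is_scalar_num(group_mepsc) && group_mepsc > 0,
             "group_mepsc must be > 0")
  check_that(is.numeric(epsc_means) && all(is.finite(epsc_means)),
             "epsc_means must be finite")
  epsc_means / group_mepsc
}

#' PHP normalization of quantal content
#'
#' Divides each treated quantal content by the mean untreated quantal
#' content. A mean ratio above 1 indicates homeostatic potentiation of
#' release.
#'
#' @param treated_qc,untreated_qc numeric vectors of per-NMJ quantal
#'   contents for the treated and untreated arm.
#' @return a list with `normalized` (per treated NMJ) and `mean_ratio`.
#' @export
php_ratio <- function(treated_qc, untreated_qc) {
  check_that(length(treated_qc) >= 1 && length(untreated_qc) >= 1,
             "both arms must be nonempty")
  m0 <- mean(untreated_qc)
  check_that(is.finite(m0) && m0 != 0, "untreated mean must be nonzero")
  norm <- treated_qc / m0
  list(normalized = norm, mean_ratio = mean(norm))
}

#' Per-stimulus mean amplitudes and cumulative profile
#'
#' Averages amplitudes across trains at each stimulus index, then forms the
#' running cumulative sum and stimulus times `t_i = (i - 1) / freq`.
#'
#' @param trains a `train_set` data frame (columns `train_id`,
#'   `stimulus_index`, `amplitude`), e.g. from [simulate_trains()].
#' @param freq stimulation frequency (Hz); defaults to the `freq` attribute
#'   of `trains`, else 60.
#' @return a `cumulative_profile` data frame with columns
#'   `stimulus_index`, `t_s`, `mean_amplitude`, `cumulative`.
#' @export
cumulative_profile <- function(trains, freq = NULL) {
  check_that(all(c("train_id", "stimulus_index", "amplitude") %in%
                   names(trains)), "trains must have train_id, stimulus_index, amplitude")
  if (is.null(freq)) freq <- attr(trains, "freq")
  if (is.null(freq)) freq <- 60
  counts <- table(trains$train_id)
  check_that(length(unique(counts)) == 1L,
             "ragged trains: unequal stimulus counts across trains")
  a <- tapply(trains$amplitude, trains$stimulus_index, mean)
  idx <- as.integer(names(a))
  check_that(identical(idx, seq_along(idx)),
             "stimulus_index must run 1..n_stim in every train")
  out <- data.frame(stimulus_index = idx,
                    t_s = (idx - 1) / freq,
                    mean_amplitude = as.numeric(a),
                    cumulative = cumsum(as.numeric(a)))
  attr(out, "freq") <- freq
  class(out) <- c("cumulative_profile", "data.frame")
  out
}

#' RRP estimate by cumulative-amplitude back-extrapolation
#'
#' Fits an ordinary least-squares line to the last `last_k` cumulative
#' amplitudes against time in seconds and back-extrapolates to `t = 0`.
#' The intercept estimates the initial pool in signal units; dividing by
#' the group mean mini amplitude converts it to quanta. During sustained
#' high-frequency stimulation the late cumulative amplitude grows linearly
#' at the replenishment-limited rate, so the intercept recovers the pool
#' released before steady state. When replenishment also refills the pool
#' during the depleting transient the intercept is biased (under
#' first-order recovery it underestimates the resting pool, because
#' depletion is shallower); the bias is reported as-is, not corrected.
#'
#' @param profile a [cumulative_profile()].
#' @param group_mepsc positive scalar group mean mini amplitude.
#' @param last_k number of trailing points in the fit (default 15).
#' @return an object of class `rrp_estimate` with `intercept`, `slope`,
#'   `rrp_quanta`, `last_k`, `freq` and `negative_intercept` flag
#'   (negative intercepts are flagged with a warning, not clamped).
#' @export
rrp_from_cumulative <- function(profile, group_mepsc, last_k = 15L) {
  stopifnot(inherits(profile, "data.frame"))
  check_that(is_scalar_num(group_mepsc) && group_mepsc > 0,
             "group_mepsc must be > 0")
  check_that(is_scalar_num(last_k) && last_k >= 2, "last_k must be >= 2")
  n <- nrow(profile)
  check_that(n >= last_k, "profile shorter than last_k")
  tail_idx <- (n - as.integer(last_k) + 1L):n
  fit <- lm(cumulative ~ t_s, data = profile[tail_idx, ])
  intercept <- unname(coef(fit)[1])
  slope <- unname(coef(fit)[2])
  neg <- intercept < 0
  if (neg) warning("back-extrapolated intercept is negative")
  structure(list(intercept = intercept, slope = slope,
                 rrp_quanta = intercept / group_mepsc,
                 group_mepsc = group_mepsc, last_k = as.integer(last_k),
                 freq = attr(profile, "freq"),
                 negative_intercept = neg),
            class = "rrp_estimate")
}

#' Release probability and paired-pulse ratio
#'
#' `p_r` is the first evoked amplitude divided by the back-extrapolated
#' cumulative intercept; PPR is the second over the first amplitude.
#' Values of `p_r` outside [0, 1] are flagged with a warning, not clamped.
#'
#' @param profile a [cumulative_profile()].
#' @param estimate an [rrp_from_cumulative()] result.
#' @return a list with `p_r` and `ppr`.
#' @export
pr_and_ppr <- function(profile, estimate) {
  stopifnot(inherits(estimate, "rrp_estimate"))
  a1 <- profile$mean_amplitude[1]
  a2 <- if (nrow(profile) >= 2) profile$mean_amplitude[2] else NA_real_
  check_that(is.finite(estimate$intercept) && estimate$intercept != 0,
             "zero intercept: p_r undefined")
  check_that(is.finite(a1) && a1 != 0, "zero first amplitude: PPR undefined")
  p_r <- a1 / estimate$intercept
  if (p_r < 0 || p_r > 1)
    warning(sprintf("p_r = %.3f outside [0, 1]", p_r))
  list(p_r = p_r, ppr = a2 / a1)
}

#' One-call RRP analysis of a train set
#'
#' Convenience wrapper: averages trains into a cumulative profile, fits the
#' back-extrapolation, and derives `p_r` and PPR.
#'
#' @inheritParams cumulative_profile
#' @inheritParams rrp_from_cumulative
#' @return an `rrp_fit` object bundling `profile`, `estimate`, `p_r`, `ppr`.
#' @export
rrp_fit <- function(trains, group_mepsc, last_k = 15L, freq = NULL) {
  profile <- cumulative_profile(trains, freq = freq)
  estimate <- rrp_from_cumulative(profile, group_mepsc, last_k = last_k)
  pp <- pr_and_ppr(profile, estimate)
  structure(list(profile = profile, estimate = estimate,
                 p_r = pp$p_r, ppr = pp$ppr),
            class = "rrp_fit")
}

#' @export
print.rrp_estimate <- function(x, ...) {
  cat(sprintf(
    "RRP estimate: intercept %.3f (slope %.3f /s), %.1f quanta (last %d points)%s\n",
    x$intercept, x$slope, x$rrp_quanta, x$last_k,
    if (x$negative_intercept) " [negative intercept]" else ""))
  invisible(x)
}

#' @export
print.rrp_fit <- function(x, ...) {
  print(x$estimate)
  cat(sprintf("p_r = %.3f, PPR = %.3f\n", x$p_r, x$ppr))
  invisible(x)
}

#' @export
plot.rrp_fit <- function(x, ...) {
  pr <- x$profile
  plot(pr$t_s, pr$cumulative, pch = 16, cex = 0.6,
       xlab = "time (s)", ylab = "cumulative amplitude", ...)
  abline(a = x$estimate$intercept, b = x$estimate$slope, col = "blue")
  tail_idx <- (nrow(pr) - x$estimate$last_k + 1L):nrow(pr)
  points(pr$t_s[tail_idx], pr$cumulative[tail_idx], pch = 16, cex = 0.6,
         col = "blue")
  invisible(x)
}
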