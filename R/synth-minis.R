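## Synthetic miniature-event traces: Poisson arrivals, lognormal amplitudes,
## biexponential kernels in Gaussian noise.

#' Parameters for miniature-event trace simulation
#'
#' Bundles and validates the settings for [simulate_minis()]. Defaults mimic
#' miniature EPSC recordings at the larval neuromuscular junction sampled at
#' 10 kHz: events arrive as a Poisson process, each event is a peak-normalized
#' biexponential transient scaled by a lognormal amplitude, and the trace is
#' embedded in white Gaussian noise.
#'
#' @param rate event rate (events/s).
#' @param amp_mean arithmetic mean of event amplitudes (signal units).
#' @param amp_cv coefficient of variation of event amplitudes (0 = identical).
#' @param rise_tau,decay_tau rise and decay time constants of the event
#'   kernel \eqn{w(t) = (1 - e^{-t/\tau_r}) e^{-t/\tau_d}} (ms).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param duration trace duration (s).
#' @param dt sampling interval (s).
#' @param polarity +1 for upward events (potentials), -1 for downward
#'   (inward currents).
#' @param seed integer RNG seed, or NULL to use the current stream.
#' @return an object of class `mini_sim_params`.
#' @export
mini_sim_params <- function(rate = 2, amp_mean = 1, amp_cv = 0.1,
                            rise_tau = 0.5, decay_tau = 5,
                            noise_sd = 0.2, duration = 60, dt = 1e-4,
                            polarity = 1L, seed = NULL) {
  check_that(is_scalar_num(rate) && rate >= 0, "rate must be >= 0")
  check_that(is_scalar_num(amp_mean) && amp_mean > 0, "amp_mean must be > 0")
  check_that(is_scalar_num(amp_cv) && amp_cv >= 0, "amp_cv must be >= 0")
  check_that(is_scalar_num(rise_tau) && rise_tau > 0, "rise_tau must be > 0")
  check_that(is_scalar_num(decay_tau) && decay_tau > rise_tau,
             "decay_tau must exceed rise_tau")
  check_that(is_scalar_num(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  check_that(is_scalar_num(duration) && duration > 0, "duration must be > 0")
  check_that(is_scalar_num(dt) && dt > 0, "dt must be > 0")
  check_that(polarity %in% c(-1, 1), "polarity must be +1 or -1")
  structure(list(rate = rate, amp_mean = amp_mean, amp_cv = amp_cv,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 noise_sd = noise_sd, duration = duration, dt = dt,
                 polarity = as.integer(polarity), seed = seed),
            class = "mini_sim_params")
}

new_trace <- function(samples, dt, units = "nA", polarity = 1L) {
  structure(list(samples = as.numeric(samples), dt = dt, units = units,
                 polarity = as.integer(polarity)),
            class = "ephys_trace")
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %d samples, dt = %g s (%.3f s), units %s, polarity %+d\n",
              length(x$samples), x$dt, length(x$samples) * x$dt,
              x$units, x$polarity))
  invisible(x)
}

#' @export
plot.ephys_trace <- function(x, xlim = NULL, ...) {
  t <- (seq_along(x$samples) - 1) * x$dt
  plot(t, x$samples, type = "l", xlab = "time (s)",
       ylab = sprintf("signal (%s)", x$units), xlim = xlim, ...)
  invisible(x)
}

#' Simulate a trace of miniature synaptic events
#'
#' Generates Poisson-arrival miniature events with lognormal amplitudes and
#' biexponential kernels, superimposed on Gaussian noise, together with the
#' ground-truth onset times and amplitudes of every inserted event.
#'
#' @param params a [mini_sim_params()] object.
#' @return a list with `trace` (class `ephys_trace`) and `truth`, a data frame
#'   with one row per event (`time_s`, `amplitude`), ordered by onset.
#' @seealso [cb_detect()] for recovering the events, [match_events()] for
#'   scoring a detection against the returned truth.
#' @export
simulate_minis <- function(params) {
  stopifnot(inherits(params, "mini_sim_params"))
  p <- params
  n_samp <- as.integer(round(p$duration / p$dt))
  with_seed(p$seed, {
    n_ev <- rpois(1, p$rate * p$duration)
    times <- sort(runif(n_ev, 0, p$duration))
    amps <- rlnorm_mean_cv(n_ev, p$amp_mean, p$amp_cv)
    x <- rnorm(n_samp, 0, p$noise_sd)
    if (n_ev > 0) {
      kern <- biexp_kernel(p$rise_tau, p$decay_tau, dt = p$dt)
      L <- length(kern)
      for (k in seq_len(n_ev)) {
        i0 <- as.integer(floor(times[k] / p$dt)) + 1L
        if (i0 > n_samp) next
        idx <- i0:min(n_samp, i0 + L - 1L)
        x[idx] <- x[idx] + amps[k] * kern[seq_along(idx)]
      }
    }
    units <- if (p$polarity < 0) "nA" else "mV"
    trace <- new_trace(p$polarity * x, p$dt, units = units,
                       polarity = p$polarity)
    truth <- data.frame(time_s = times, amplitude = amps)
    list(trace = trace, truth = truth, params = p)
  })
}

# Peak-normalized biexponential kernel sampled at dt (s); taus in ms.
# Length defaults to 6 decay time constants, enough for the tail to fall
# below 0.3% of the peak.
biexp_kernel <- function(rise_tau, decay_tau, dt, length_ms = 6 * decay_tau) {
  t_ms <- seq(0, length_ms, by = dt * 1e3)
  w <- (1 - exp(-t_ms / rise_tau)) * exp(-t_ms / decay_tau)
  w / max(w)
}
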