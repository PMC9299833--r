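## Synthetic 60 Hz depression trains from a vesicle depletion-replenishment
## quantal model.

#' Parameters of the depletion-replenishment train model
#'
#' Settings for [simulate_trains()]. The model releases a fraction `pr` of
#' the current readily-releasable pool at every stimulus and recovers toward
#' the resting pool size `N0` by first-order replenishment between stimuli:
#' \deqn{A_i = q \, p_r \, N_i (1 + \epsilon_i), \qquad
#'       N_{i+1} = N_i(1-p_r) + k \Delta t \,[N_0 - N_i(1-p_r)]}
#' with \eqn{\Delta t = 1/\mathrm{freq}}, \eqn{N_1 = N_0} and
#' \eqn{\epsilon_i \sim N(0, \mathrm{trial\_noise\_cv})}, clipped to
#' \eqn{[0, N_0]}.
#'
#' @param N0 resting pool size (vesicles); ground-truth RRP.
#' @param pr release probability per stimulus, in (0, 1].
#' @param q quantal size (signal units per vesicle).
#' @param k_replenish replenishment rate constant (1/s) toward `N0`.
#' @param n_stim stimuli per train (default 60).
#' @param freq stimulation frequency (Hz, default 60).
#' @param n_trains independent trains per cell (default 5).
#' @param trial_noise_cv multiplicative amplitude noise CV per stimulus.
#' @param seed integer RNG seed or NULL.
#' @return an object of class `quantal_model_params`.
#' @export
quantal_model_params <- function(N0 = 500, pr = 0.5, q = 1,
                                 k_replenish = 0, n_stim = 60L, freq = 60,
                                 n_trains = 5L, trial_noise_cv = 0,
                                 seed = NULL) {
  check_that(is_scalar_num(N0) && N0 >= 1, "N0 must be >= 1")
  check_that(is_scalar_num(pr) && pr >= 0 && pr <= 1, "pr must be in [0, 1]")
  check_that(is_scalar_num(q) && q > 0, "q must be > 0")
  check_that(is_scalar_num(k_replenish) && k_replenish >= 0,
             "k_replenish must be >= 0")
  check_that(is_scalar_num(n_stim) && n_stim >= 1, "n_stim must be >= 1")
  check_that(is_scalar_num(freq) && freq > 0, "freq must be > 0")
  check_that(is_scalar_num(n_trains) && n_trains >= 1, "n_trains must be >= 1")
  check_that(is_scalar_num(trial_noise_cv) && trial_noise_cv >= 0,
             "trial_noise_cv must be >= 0")
  structure(list(N0 = N0, pr = pr, q = q, k_replenish = k_replenish,
                 n_stim = as.integer(n_stim), freq = freq,
                 n_trains = as.integer(n_trains),
                 trial_noise_cv = trial_noise_cv, seed = seed),
            class = "quantal_model_params")
}

# Noise-free pool trajectory and amplitudes of the recurrence; shared by the
# generator and nothing else (tests carry their own independent oracle).
depletion_recurrence <- function(N0, pr, q, k_replenish, n_stim, freq) {
  dt <- 1 / freq
  N <- numeric(n_stim)
  N[1] <- N0
  for (i in seq_len(n_stim - 1L)) {
    surv <- N[i] * (1 - pr)
    N[i + 1L] <- min(max(surv + k_replenish * dt * (N0 - surv), 0), N0)
  }
  list(N = N, A = q * pr * N)
}

#' Simulate high-frequency stimulus trains
#'
#' Draws `n_trains` independent trains of per-stimulus evoked amplitudes
#' from the depletion-replenishment model described in
#' [quantal_model_params()].
#'
#' @param params a [quantal_model_params()] object.
#' @return a list with `trains`, a data frame with columns `cell_id`,
#'   `train_id`, `stimulus_index`, `amplitude` (class `train_set`), and
#'   `truth` holding the generating `N0`, `pr`, `q` and the noise-free
#'   amplitude trajectory.
#' @export
simulate_trains <- function(params, cell_id = "cell1") {
  stopifnot(inherits(params, "quantal_model_params"))
  p <- params
  base <- depletion_recurrence(p$N0, p$pr, p$q, p$k_replenish, p$n_stim, p$freq)
  with_seed(p$seed, {
    rows <- lapply(seq_len(p$n_trains), function(tr) {
      eps <- if (p$trial_noise_cv > 0)
        rnorm(p$n_stim, 0, p$trial_noise_cv) else numeric(p$n_stim)
      data.frame(cell_id = cell_id, train_id = tr,
                 stimulus_index = seq_len(p$n_stim),
                 amplitude = base$A * (1 + eps))
    })
    trains <- do.call(rbind, rows)
    class(trains) <- c("train_set", "data.frame")
    attr(trains, "freq") <- p$freq
    list(trains = trains,
         truth = list(N0 = p$N0, pr = p$pr, q = p$q,
                      k_replenish = p$k_replenish,
                      noise_free_amplitude = base$A,
                      pool_trajectory = base$N),
         params = p)
  })
}
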