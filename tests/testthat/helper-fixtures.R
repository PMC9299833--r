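# Shared fixtures, built in code.

# Axis-aligned square polygon (nm).
square_polygon <- function(side = 2000) {
  cbind(c(0, side, side, 0), c(0, 0, side, side))
}

# Minimal event table for match_events tests.
make_event_table <- function(times_s, amplitudes = rep(1, length(times_s))) {
  out <- data.frame(onset_s = times_s, amplitude = amplitudes,
                    offset = rep(0, length(times_s)),
                    criterion = rep(Inf, length(times_s)))
  class(out) <- c("event_table", "data.frame")
  out
}

# Bouton geometry with hand-placed channels.
make_geometry <- function(polygon, reference, target) {
  structure(list(polygon = polygon,
                 reference = as.matrix(reference),
                 target = as.matrix(target)),
            class = "bouton_geometry")
}

# Independent oracle for the depletion-replenishment recurrence: a literal
# re-iteration, kept separate from the package's internals.
oracle_recurrence <- function(N0, pr, q, k, n_stim, freq) {
  dt <- 1 / freq
  N <- N0
  A <- numeric(n_stim)
  for (i in seq_len(n_stim)) {
    A[i] <- q * pr * N
    surv <- N * (1 - pr)
    N <- min(max(surv + k * dt * (N0 - surv), 0), N0)
  }
  A
}

# Closed-form OLS of y on x via normal equations (independent of lm()).
oracle_ols <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  b <- (n * sum(x * y) - sx * sy) / (n * sum(x * x) - sx^2)
  a <- (sy - b * sx) / n
  c(intercept = a, slope = b)
}
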