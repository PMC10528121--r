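# Independent oracles used across the suite.

# Fixed-step classical fourth-order Runge-Kutta integration of dv/dt = A v.
# Works for real A (Kolmogorov forward equation) and complex A = -iH
# (Schroedinger equation); independent of the propagator implementations.
rk4_evolve <- function(A, v0, t, step = 1e-4) {
  n_steps <- ceiling(t / step)
  h <- t / n_steps
  v <- v0
  for (k in seq_len(n_steps)) {
    k1 <- A %*% v
    k2 <- A %*% (v + h / 2 * k1)
    k3 <- A %*% (v + h / 2 * k2)
    k4 <- A %*% (v + h * k3)
    v <- v + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.vector(v)
}

# Random probability vector over n states.
random_prob <- function(n) {
  p <- stats::runif(n)
  p / sum(p)
}

# Random normalized complex amplitude vector over n states.
random_amps <- function(n) {
  a <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  a / sqrt(sum(Mod(a)^2))
}

# Minimal trajectory object with prescribed point predictions, for unit
# tests of rmse() that do not involve any dynamics.
fixed_trajectory <- function(times, point_predictions, n = 11L) {
  structure(list(times = times,
                 distributions = matrix(1 / n, length(times), n),
                 point_predictions = point_predictions,
                 model_tag = "markov", readout = "expectation"),
            class = "prediction_trajectory")
}

# Small epoch set built from an explicit channels x samples x trials array
# with simple metadata; window chosen so samples land on integer ms.
toy_epochs <- function(data, sampling_rate = 250, window = c(-1300, 950),
                       condition = NULL, rt = NULL, response_given = NULL) {
  n_tr <- dim(data)[3]
  if (is.null(condition))
    condition <- rep(c("match", "mismatch"), length.out = n_tr)
  if (is.null(rt)) rt <- rep(0.5, n_tr)
  if (is.null(response_given)) response_given <- rep(TRUE, n_tr)
  meta <- data.frame(condition = condition, reaction_time_s = rt,
                     response_given = response_given,
                     baseline_start_ms = window[1],
                     baseline_end_ms = min(window[1] + 600, window[2]))
  labs <- default_montage()[seq_len(dim(data)[1])]
  epoch_set(data, sampling_rate, window, labs, meta)
}
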