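#' Markov birth-death rate parameters
#'
#' The continuous-time Markov model lets the definite reliability state hop
#' only between neighbouring levels: `beta_plus` is the rate of moving one
#' level up (reliability expectation increasing), `beta_minus` the rate of
#' moving one level down.  The self-intensity `alpha = beta_plus +
#' beta_minus` is the total rate of leaving the current level and is derived,
#' not free.
#'
#' @param beta_plus Upward transition rate, > 0 (per unit model time).
#' @param beta_minus Downward transition rate, > 0.
#' @return An `intensity_params` object with fields `beta_plus`,
#'   `beta_minus`, `alpha`.
#' @examples
#' intensity_params(0.6, 0.4)$alpha  # 1
#' @export
intensity_params <- function(beta_plus = 0.6, beta_minus = 0.4) {
  if (!is.finite(beta_plus) || !is.finite(beta_minus) ||
      beta_plus <= 0 || beta_minus <= 0)
    stop("beta_plus and beta_minus must be positive", call. = FALSE)
  structure(list(beta_plus = beta_plus, beta_minus = beta_minus,
                 alpha = beta_plus + beta_minus),
            class = "intensity_params")
}

#' Build the birth-death intensity matrix
#'
#' Constructs the generator `K` of the continuous-time chain, oriented for
#' column-vector evolution `d phi/dt = K phi`: column `j` holds the
#' probability flow out of state `j`, so `K[j+1, j] = beta_plus` (up),
#' `K[j-1, j] = beta_minus` (down), and the diagonal makes every column sum
#' to zero.  Interior diagonals are `-alpha`; the reflecting boundaries drop
#' the out-of-range flow, giving `-beta_plus` at state 0 and `-beta_minus`
#' at state `n-1`.
#'
#' @param params An [intensity_params()].
#' @param space A [state_space()].
#' @return An `intensity_matrix` object: fields `K` (n x n), `params`,
#'   `space`.
#' @examples
#' build_intensity_matrix(intensity_params(0.5, 0.5), state_space(2))$K
#' @export
build_intensity_matrix <- function(params = intensity_params(),
                                   space = state_space(11L)) {
  stopifnot(inherits(params, "intensity_params"),
            inherits(space, "state_space"))
  n <- space$n
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    if (j < n) K[j + 1L, j] <- params$beta_plus
    if (j > 1) K[j - 1L, j] <- params$beta_minus
    K[j, j] <- -sum(K[, j])
  }
  structure(list(K = K, params = params, space = space),
            class = "intensity_matrix")
}

#' Evolve a probability distribution under the Kolmogorov forward equation
#'
#' Solves `d phi/dt = K phi`, i.e. `phi(t) = expm(t K) phi(0)`, via a dense
#' Pade matrix exponential.  Probability is conserved to 1e-9 by
#' construction of `K` (zero column sums).
#'
#' @param phi0 A `markov_state` (see [uniform_initial()],
#'   [weighted_initial()]).
#' @param gen An `intensity_matrix` from [build_intensity_matrix()].
#' @param t Nonnegative model time.
#' @return The evolved `markov_state` at time `phi0$time + t`.
#' @export
evolve_markov <- function(phi0, gen, t) {
  stopifnot(inherits(phi0, "markov_state"), inherits(gen, "intensity_matrix"))
  if (!is.finite(t) || t < 0) stop("t must be >= 0", call. = FALSE)
  if (length(phi0$probs) != gen$space$n)
    stop("state dimension does not match the generator", call. = FALSE)
  validate_state(phi0)
  if (t == 0) return(phi0)
  P <- as.matrix(Matrix::expm(t * gen$K))
  p <- as.numeric(P %*% phi0$probs)
  p[p < 0 & p > -1e-12] <- 0           # clip exponentiation round-off
  new_markov_state(p, time = phi0$time + t)
}

#' Rating prediction from a Markov state
#'
#' The chain inhabits a definite level at all times, so the predicted
#' distribution over reported ratings is the state occupancy itself:
#' `P(R = i) = p_i`.
#'
#' @param phi A `markov_state`.
#' @return Numeric vector of `P(R = i)` for `i = 0 ... n-1`.
#' @export
markov_predict <- function(phi) {
  stopifnot(inherits(phi, "markov_state"))
  validate_state(phi)
  phi$probs
}

#' Stationary distribution of the birth-death chain
#'
#' Detailed balance gives `pi_i` proportional to `(beta_plus/beta_minus)^i`;
#' useful as the long-time limit of [evolve_markov()].
#'
#' @param params An [intensity_params()].
#' @param space A [state_space()].
#' @return Numeric probability vector of length `n`.
#' @export
markov_stationary <- function(params, space) {
  w <- (params$beta_plus / params$beta_minus)^(space$labels)
  w / sum(w)
}
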