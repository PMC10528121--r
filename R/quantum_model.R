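#' Hamiltonian parameters for the quantum walk
#'
#' The quantum model evolves a superposed amplitude vector under a real
#' symmetric Hamiltonian.  Its diagonal is a linear potential `mu_x =
#' mu_slope * x` driving amplitude towards higher reliability levels (the
#' system mostly agrees with the participant, so expectation energy accrues
#' linearly); `sigma2` is the nearest-neighbour off-diagonal coupling that
#' diffuses amplitude between adjacent levels; `z` couples the two extreme
#' levels (corners of the matrix) directly, allowing an abrupt collapse from
#' "fully reliable" to "totally unreliable" without passing through
#' intermediate levels.
#'
#' @param mu_slope Potential slope (energy per state index); analysis
#'   default 0.05.
#' @param sigma2 Nearest-neighbour coupling, >= 0; analysis default 0.7.
#' @param z Corner coupling between states 0 and n-1, >= 0; default 0.2.
#' @return A `hamiltonian_params` object.
#' @export
hamiltonian_params <- function(mu_slope = 0.05, sigma2 = 0.7, z = 0.2) {
  if (!all(is.finite(c(mu_slope, sigma2, z))) || sigma2 < 0 || z < 0)
    stop("need finite mu_slope and nonnegative sigma2, z", call. = FALSE)
  structure(list(mu_slope = mu_slope, sigma2 = sigma2, z = z),
            class = "hamiltonian_params")
}

#' Build the quantum-walk Hamiltonian
#'
#' `H[i, i] = mu_slope * i`, `H[i, i+1] = H[i+1, i] = sigma2`,
#' `H[0, n-1] = H[n-1, 0] = z`, all other entries zero.  With the defaults
#' and `n = 11` the diagonal runs 0, 0.05, ..., 0.50, the off-diagonals are
#' 0.7 and the corners 0.2.
#'
#' @param params A [hamiltonian_params()].
#' @param space A [state_space()].
#' @return A `hamiltonian` object: fields `H` (n x n symmetric), `params`,
#'   `space`.
#' @export
build_hamiltonian <- function(params = hamiltonian_params(),
                              space = state_space(11L)) {
  stopifnot(inherits(params, "hamiltonian_params"),
            inherits(space, "state_space"))
  n <- space$n
  H <- matrix(0, n, n)
  diag(H) <- params$mu_slope * space$labels
  for (i in seq_len(n - 1L)) H[i, i + 1L] <- H[i + 1L, i] <- params$sigma2
  if (n > 2L) H[1L, n] <- H[n, 1L] <- params$z  # corners distinct from
                                                # neighbours only for n > 2
  structure(list(H = H, params = params, space = space),
            class = "hamiltonian")
}

#' Unitary (Schroedinger) evolution of a wave state
#'
#' `psi(t) = exp(-i t H) psi(0)`, computed exactly through the symmetric
#' eigendecomposition of `H`, so the squared-modulus norm is conserved to
#' machine precision.
#'
#' @param psi0 A `wave_state`.
#' @param gen A `hamiltonian` from [build_hamiltonian()].
#' @param t Nonnegative model time.  (Negative times arise internally for
#'   time-reversal checks; the public contract is `t >= 0`.)
#' @return The evolved `wave_state` at time `psi0$time + t`.
#' @export
evolve_quantum <- function(psi0, gen, t) {
  stopifnot(inherits(psi0, "wave_state"), inherits(gen, "hamiltonian"))
  if (!is.finite(t) || t < 0) stop("t must be >= 0", call. = FALSE)
  if (length(psi0$amps) != gen$space$n)
    stop("state dimension does not match the generator", call. = FALSE)
  validate_state(psi0)
  if (t == 0) return(psi0)
  .evolve_quantum_signed(psi0, gen, t)
}

# internal: allows negative t for reversibility checks
.evolve_quantum_signed <- function(psi0, gen, t) {
  e <- eigen(gen$H, symmetric = TRUE)
  a <- e$vectors %*% (exp(-1i * t * e$values) * crossprod(e$vectors, psi0$amps))
  new_wave_state(as.complex(a), time = psi0$time + t)
}

#' Born-rule readout of a wave state
#'
#' The probability of a reliability report at level `i` is the squared
#' modulus of the amplitude: `Q(R = i) = |q_i|^2`.
#'
#' @param psi A `wave_state`.
#' @return Numeric vector of report probabilities over `0 ... n-1`.
#' @export
born_probabilities <- function(psi) {
  stopifnot(inherits(psi, "wave_state"))
  validate_state(psi)
  Mod(psi$amps)^2
}
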