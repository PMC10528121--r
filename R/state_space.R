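#' Discrete reliability state space
#'
#' The models operate on a coarse-grained reliability scale with `n`
#' orthonormal basis states indexed `0 ... n-1`, where 0 means "totally
#' unreliable" and `n-1` means "fully reliable".  The analysis scale has
#' `n = 11` states; the two-state and five-state spaces are useful for
#' closed-form checks.
#'
#' @param n Integer number of basis states, at least 2.
#' @return An object of class `state_space` with fields `n` and `labels`
#'   (the integer state indices `0:(n-1)`).
#' @examples
#' state_space(11)
#' @export
state_space <- function(n = 11L) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("state space needs at least 2 states", call. = FALSE)
  structure(list(n = n, labels = 0:(n - 1L)), class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("Reliability state space with", x$n, "levels (0 =",
      "totally unreliable, ", x$n - 1L, "= fully reliable)\n")
  invisible(x)
}

#' Map continuous reliability ratings to discrete states
#'
#' Ratings on the 0--100 percent slider are binned onto the 11-state scale:
#' ratings below 9 map to state 0, ratings in \[9, 18) to state 1, and so on
#' in bins of width 9 up to \[81, 90) -> 9; ratings of 90 or more map to
#' state 10.  Only the 11-state space carries this calibration; other sizes
#' are rejected.
#'
#' @param rating Numeric vector of ratings in \[0, 100\] (percent).
#' @param space A [state_space()] with `n = 11`.
#' @return Integer vector of state indices in `0:10`.
#' @examples
#' map_rating_to_state(48.9)  # 5
#' @export
map_rating_to_state <- function(rating, space = state_space(11L)) {
  stopifnot(inherits(space, "state_space"))
  if (space$n != 11L)
    stop("the rating-to-state binning is defined for the 11-state scale only",
         call. = FALSE)
  if (any(!is.finite(rating)) || any(rating < 0) || any(rating > 100))
    stop("ratings must lie in [0, 100]", call. = FALSE)
  # bins [0,9), [9,18), ..., [81,90), [90,100]
  breaks <- seq(9, 90, by = 9)
  as.integer(findInterval(rating, breaks))
}

#' Single rating observation
#'
#' One reliability rating with its block label and mapped state.
#' `block_index` is 0 for the post-practice rating, `1:n_blocks` for the
#' experimental blocks, and -1 for the pre-practice rating collected before
#' any interaction with the system.
#'
#' @param block_index Integer block label (>= -1).
#' @param raw_rating Rating in \[0, 100\] percent.
#' @param space State space used for the mapping (11 states).
#' @return A one-row `data.frame` with columns `block_index`, `raw_rating`,
#'   `state`.
#' @export
rating_observation <- function(block_index, raw_rating,
                               space = state_space(11L)) {
  block_index <- as.integer(block_index)
  if (any(block_index < -1L))
    stop("block_index must be >= -1 (-1 = pre-practice)", call. = FALSE)
  data.frame(block_index = block_index,
             raw_rating = as.numeric(raw_rating),
             state = map_rating_to_state(raw_rating, space))
}

# ---- state vectors ---------------------------------------------------------

new_markov_state <- function(probs, time = 0) {
  structure(list(probs = as.numeric(probs), time = as.numeric(time)),
            class = "markov_state")
}

new_wave_state <- function(amps, time = 0) {
  structure(list(amps = as.complex(amps), time = as.numeric(time)),
            class = "wave_state")
}

#' Validate a Markov or wave state vector
#'
#' A `markov_state` holds a probability distribution over the reliability
#' levels (entries nonnegative, summing to one); a `wave_state` holds
#' complex amplitudes whose squared moduli sum to one.
#'
#' @param state A `markov_state` or `wave_state`.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_state <- function(state) {
  if (inherits(state, "markov_state")) {
    p <- state$probs
    if (any(p < -1e-12))
      stop("markov_state has negative probabilities", call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9)
      stop("markov_state probabilities do not sum to 1", call. = FALSE)
  } else if (inherits(state, "wave_state")) {
    if (abs(sum(Mod(state$amps)^2) - 1) > 1e-9)
      stop("wave_state squared moduli do not sum to 1", call. = FALSE)
  } else {
    stop("not a markov_state or wave_state", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.markov_state <- function(x, ...) {
  cat("markov_state at t =", x$time, "\n")
  print(round(x$probs, 6))
  invisible(x)
}

#' @export
print.wave_state <- function(x, ...) {
  cat("wave_state at t =", x$time, "\n")
  print(round(x$amps, 6))
  invisible(x)
}

#' Uniform initial state
#'
#' The agnostic initial condition: for the Markov model, equal probability
#' `1/n` on every reliability level; for the quantum model, equal real
#' amplitude `1/sqrt(n)` so every level carries equal Born weight.
#'
#' @param space A [state_space()].
#' @param flavor `"markov"` (probability vector) or `"quantum"` (amplitudes).
#' @return A `markov_state` or `wave_state` at time 0.
#' @examples
#' uniform_initial(state_space(5), "markov")$probs  # all 0.2
#' @export
uniform_initial <- function(space, flavor = c("markov", "quantum")) {
  stopifnot(inherits(space, "state_space"))
  flavor <- match.arg(flavor)
  if (flavor == "markov") new_markov_state(rep(1 / space$n, space$n))
  else new_wave_state(rep(1 / sqrt(space$n), space$n))
}

# 7-point stencils used for the weighted initial state on the 11-level scale:
# peak at the start state, symmetric decay over the three neighbours each
# side, zero beyond.
.markov_stencil  <- c(0.025, 0.0625, 0.17, 0.5, 0.17, 0.0625, 0.025)
.quantum_stencil <- c(0.17, 0.24, 0.41, 0.71, 0.41, 0.24, 0.17)

#' Weighted (participant-anchored) initial state
#'
#' Centres a fixed 7-point stencil on the state mapped from the
#' participant's post-practice reliability rating: Markov weights
#' `(0.025, 0.0625, 0.17, 0.5, 0.17, 0.0625, 0.025)` or quantum amplitudes
#' `(0.17, 0.24, 0.41, 0.71, 0.41, 0.24, 0.17)`, zero elsewhere.  Stencil
#' entries falling off the scale are truncated.  The raw stencils do not
#' normalise exactly (the Markov weights sum to 1.015 and the quantum
#' squared amplitudes to 1.0133), so by default the vector is rescaled to a
#' valid state before use in evolution; `normalize = FALSE` returns the raw
#' stencil verbatim.
#'
#' @param space A [state_space()] (the stencil is calibrated to `n = 11`).
#' @param start_state Integer state index the stencil is centred on.
#' @param flavor `"markov"` or `"quantum"`.
#' @param normalize Rescale to satisfy the state invariant (default `TRUE`).
#' @return A `markov_state` or `wave_state` at time 0.
#' @examples
#' weighted_initial(state_space(11), 5, "markov", normalize = FALSE)$probs
#' @export
weighted_initial <- function(space, start_state,
                             flavor = c("markov", "quantum"),
                             normalize = TRUE) {
  stopifnot(inherits(space, "state_space"))
  flavor <- match.arg(flavor)
  start_state <- as.integer(start_state)
  if (length(start_state) != 1L || is.na(start_state) ||
      start_state < 0L || start_state > space$n - 1L)
    stop("start_state must be a state index in 0..", space$n - 1L,
         call. = FALSE)
  stencil <- if (flavor == "markov") .markov_stencil else .quantum_stencil
  v <- numeric(space$n)
  idx <- start_state + (-3:3)            # 0-based stencil positions
  keep <- idx >= 0L & idx <= space$n - 1L
  v[idx[keep] + 1L] <- stencil[keep]
  if (flavor == "markov") {
    if (normalize) v <- v / sum(v)
    new_markov_state(v)
  } else {
    if (normalize) v <- v / sqrt(sum(v^2))
    new_wave_state(v)
  }
}

#' Read a ratings table
#'
#' Reads a CSV of per-block reliability ratings with header columns
#' `block_index` and `raw_rating` (percent); a `state` column, if present,
#' is ignored and recomputed from the binning.
#'
#' @param path Path to the CSV file.
#' @param space State space for the mapping.
#' @return A `data.frame` of rating observations.
#' @export
read_ratings <- function(path, space = state_space(11L)) {
  if (!file.exists(path))
    stop("ratings file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  need <- c("block_index", "raw_rating")
  if (!all(need %in% names(d)))
    stop("ratings CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  rating_observation(d$block_index, d$raw_rating, space)
}

#' Write a ratings table
#'
#' @param ratings Data frame from [rating_observation()] or
#'   [generate_rating_trajectory()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}
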