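#' Model prediction trajectory over a time schedule
#'
#' Evolves a single initial state (no re-initialisation between ratings)
#' under the matching generator and records, at each scheduled time, the
#' predicted distribution over reliability levels and its expected-state
#' point prediction `sum(i * P(R = i))`.
#'
#' @param initial A `markov_state` or `wave_state`.
#' @param gen The matching generator: `intensity_matrix` for a
#'   `markov_state`, `hamiltonian` for a `wave_state`.
#' @param schedule Strictly increasing vector of nonnegative model times.
#' @param readout Point prediction: `"expectation"` (default, smooth) or
#'   `"mode"` (most probable level).
#' @return A `prediction_trajectory`: `times`, `distributions` (one row per
#'   time), `point_predictions`, `model_tag`.
#' @export
predict_trajectory <- function(initial, gen, schedule,
                               readout = c("expectation", "mode")) {
  readout <- match.arg(readout)
  if (length(schedule) == 0L || any(!is.finite(schedule)) ||
      any(schedule < 0) || any(diff(schedule) <= 0))
    stop("schedule must be non-empty, nonnegative and strictly increasing",
         call. = FALSE)
  m_ok <- inherits(initial, "markov_state") && inherits(gen, "intensity_matrix")
  q_ok <- inherits(initial, "wave_state") && inherits(gen, "hamiltonian")
  if (!m_ok && !q_ok)
    stop("initial state and generator flavors do not match", call. = FALSE)
  n <- gen$space$n
  labels <- gen$space$labels
  dist <- matrix(NA_real_, length(schedule), n)
  if (m_ok) {
    # step incrementally; the propagator for each distinct dt is cached
    cache <- list()
    phi <- initial
    prev <- 0
    for (k in seq_along(schedule)) {
      dt <- schedule[k] - prev
      if (dt > 0) {
        key <- format(dt, digits = 15)
        if (is.null(cache[[key]]))
          cache[[key]] <- as.matrix(Matrix::expm(dt * gen$K))
        p <- as.numeric(cache[[key]] %*% phi$probs)
        p[p < 0 & p > -1e-12] <- 0
        phi <- new_markov_state(p, time = schedule[k])
      }
      dist[k, ] <- markov_predict(phi)
      prev <- schedule[k]
    }
    tag <- "markov"
  } else {
    e <- eigen(gen$H, symmetric = TRUE)
    c0 <- crossprod(e$vectors, initial$amps)
    for (k in seq_along(schedule)) {
      a <- e$vectors %*% (exp(-1i * schedule[k] * e$values) * c0)
      dist[k, ] <- Mod(a)^2
    }
    tag <- "quantum"
  }
  point <- if (readout == "expectation") as.numeric(dist %*% labels)
           else labels[max.col(dist, ties.method = "first")]
  structure(list(times = as.numeric(schedule), distributions = dist,
                 point_predictions = point, model_tag = tag,
                 readout = readout),
            class = "prediction_trajectory")
}

#' Root mean square error of a trajectory against observed ratings
#'
#' Compares the trajectory's point predictions with observed (mapped)
#' reliability states: `sqrt(mean((prediction - observed_state)^2))` over
#' the supplied observations.
#'
#' @param traj A [predict_trajectory()] result.
#' @param observations Data frame with `block_index` and `state` columns.
#' @param block_times Named numeric vector mapping block index (as name) to
#'   model time; every observed block must be present and its time must be
#'   in the trajectory schedule.
#' @return Nonnegative scalar RMSE on the state scale.
#' @export
rmse <- function(traj, observations, block_times) {
  stopifnot(inherits(traj, "prediction_trajectory"))
  bl <- as.character(observations$block_index)
  if (!all(bl %in% names(block_times)))
    stop("no time given for block(s): ",
         paste(setdiff(bl, names(block_times)), collapse = ", "),
         call. = FALSE)
  tt <- unname(block_times[bl])
  idx <- match(round(tt, 9), round(traj$times, 9))
  if (anyNA(idx))
    stop("block time(s) missing from the trajectory schedule", call. = FALSE)
  sqrt(mean((traj$point_predictions[idx] - observations$state)^2))
}

#' Compare Markov and quantum models on one session's ratings
#'
#' Builds both models from the same initial state — by default the weighted
#' stencil centred on the state mapped from the post-practice rating (block
#' 0) — evolves each across the session with block-end rating times
#' `t = block * trials_per_block * time_scale`, and scores both against the
#' observed block ratings (blocks 1..n; the block-0 rating anchors the
#' initial state and is not scored).
#'
#' @param ratings Data frame of rating observations (`block_index`,
#'   `raw_rating`, optionally `state`; see [rating_observation()]).
#' @param markov A [intensity_params()].
#' @param quantum A [hamiltonian_params()].
#' @param time_scale Model time per trial (default 1).
#' @param init `"weighted"` or `"uniform"` initial state.
#' @param trials_per_block Trials in each block (default 28).
#' @param space State space (default 11 levels).
#' @param readout Point-prediction readout, as in [predict_trajectory()].
#' @return A `comparison_result`: `rmse_markov`, `rmse_quantum`,
#'   `per_block_error` (block, time, observed state, both predictions),
#'   plus the two trajectories.
#' @export
compare_models <- function(ratings,
                           markov = intensity_params(),
                           quantum = hamiltonian_params(),
                           time_scale = 1,
                           init = c("weighted", "uniform"),
                           trials_per_block = 28L,
                           space = state_space(11L),
                           readout = "expectation") {
  init <- match.arg(init)
  if (!"state" %in% names(ratings))
    ratings$state <- map_rating_to_state(ratings$raw_rating, space)
  obs <- ratings[ratings$block_index >= 1L, , drop = FALSE]
  if (nrow(obs) < 2L)
    stop("need at least 2 scored rating observations", call. = FALSE)
  if (init == "weighted") {
    anchor <- ratings$state[ratings$block_index == 0L]
    if (length(anchor) != 1L)
      stop("weighted init needs exactly one post-practice (block 0) rating",
           call. = FALSE)
    phi0 <- weighted_initial(space, anchor, "markov")
    psi0 <- weighted_initial(space, anchor, "quantum")
  } else {
    phi0 <- uniform_initial(space, "markov")
    psi0 <- uniform_initial(space, "quantum")
  }
  blocks <- sort(unique(obs$block_index))
  times <- blocks * trials_per_block * time_scale
  block_times <- stats::setNames(times, blocks)
  Km <- build_intensity_matrix(markov, space)
  Hq <- build_hamiltonian(quantum, space)
  tm <- predict_trajectory(phi0, Km, times, readout)
  tq <- predict_trajectory(psi0, Hq, times, readout)
  obs <- obs[order(obs$block_index), , drop = FALSE]
  per_block <- data.frame(block = blocks, time = times,
                          observed_state = obs$state,
                          markov_prediction = tm$point_predictions,
                          quantum_prediction = tq$point_predictions)
  structure(list(rmse_markov = rmse(tm, obs, block_times),
                 rmse_quantum = rmse(tq, obs, block_times),
                 per_block_error = per_block,
                 trajectory_markov = tm, trajectory_quantum = tq,
                 init = init, time_scale = time_scale),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Model comparison over", nrow(x$per_block_error), "block ratings",
      sprintf("(init = %s, time scale = %g/trial)\n", x$init, x$time_scale))
  cat(sprintf("  Markov RMSE:  %.4f\n  Quantum RMSE: %.4f\n",
              x$rmse_markov, x$rmse_quantum))
  invisible(x)
}
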