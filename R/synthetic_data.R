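#' Session design for the synthetic Wizard-of-Oz experiment
#'
#' The emulated study: 20 blocks of 28 trials (560 in total), each trial a
#' real-vs-fake face classification followed by feedback from an ostensibly
#' autonomous AI whose answer is scripted to agree with the participant on
#' 75% of trials (match) and disagree on 25% (mismatch), with exact
#' per-block counts and per-block shuffled order.  The stimulus manifest
#' holds 294 real and 294 AI-synthesised face identifiers, each shown at
#' most once.
#'
#' @param n_blocks Number of experimental blocks (default 20).
#' @param trials_per_block Trials per block (default 28).
#' @param match_fraction Fraction of match trials per block (default 0.75);
#'   `match_fraction * trials_per_block` must be an integer.
#' @param n_real_images,n_fake_images Manifest sizes (default 294 each).
#' @param rt_mean_s,rt_sd_s Mean and SD (seconds) of the lognormal
#'   reaction-time distribution; draws beyond 2 s become timeouts.
#' @param seed Integer seed for the session generator.
#' @return A `session_config` object.
#' @export
session_config <- function(n_blocks = 20L, trials_per_block = 28L,
                           match_fraction = 0.75,
                           n_real_images = 294L, n_fake_images = 294L,
                           rt_mean_s = 0.8, rt_sd_s = 0.3, seed = 1L) {
  n_match <- match_fraction * trials_per_block
  if (abs(n_match - round(n_match)) > 1e-9)
    stop("match_fraction * trials_per_block must be an integer",
         call. = FALSE)
  if (match_fraction <= 0 || match_fraction > 1)
    stop("match_fraction must be in (0, 1]", call. = FALSE)
  if (rt_mean_s <= 0 || rt_sd_s <= 0)
    stop("reaction-time parameters must be positive", call. = FALSE)
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 match_fraction = match_fraction,
                 n_real_images = as.integer(n_real_images),
                 n_fake_images = as.integer(n_fake_images),
                 rt_mean_s = rt_mean_s, rt_sd_s = rt_sd_s,
                 seed = as.integer(seed)),
            class = "session_config")
}

# moment-matched lognormal parameters from mean/sd of the RT itself
.lognormal_pars <- function(m, s) {
  list(meanlog = log(m^2 / sqrt(m^2 + s^2)),
       sdlog = sqrt(log(1 + s^2 / m^2)))
}

#' Generate a synthetic Wizard-of-Oz session
#'
#' Produces the full trial log and stimulus manifest: per block, exactly
#' `match_fraction * trials_per_block` match trials in seeded random order;
#' stimuli drawn without replacement from the manifest with a 50/50
#' real/fake presentation balance; reaction times drawn from the lognormal
#' and truncated at 2 s (slower draws become timeout trials with no AI
#' feedback).  The AI response is derived from the participant response and
#' the scripted condition: identical on match trials, opposite on mismatch.
#'
#' @param config A [session_config()].
#' @return A `woz_session`: `trials` (data frame: `block`,
#'   `index_in_block`, `condition`, `stimulus_id`, `stimulus_class`,
#'   `participant_response`, `ai_response`, `reaction_time_s`) and
#'   `manifest` (data frame: `image_id`, `class`, `used`).
#' @export
generate_session <- function(config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  n_trials <- config$n_blocks * config$trials_per_block
  per_class <- n_trials / 2
  if (per_class > config$n_real_images || per_class > config$n_fake_images)
    stop("stimulus manifest too small for ", n_trials, " trials",
         call. = FALSE)
  if (n_trials %% 2L != 0L)
    stop("trial count must be even for a 50/50 class balance", call. = FALSE)
  set.seed(config$seed)
  manifest <- data.frame(
    image_id = c(sprintf("real_%03d", seq_len(config$n_real_images)),
                 sprintf("fake_%03d", seq_len(config$n_fake_images))),
    class = rep(c("real", "fake"),
                c(config$n_real_images, config$n_fake_images)))
  shown <- c(sample(manifest$image_id[manifest$class == "real"], per_class),
             sample(manifest$image_id[manifest$class == "fake"], per_class))
  shown <- sample(shown)                       # presentation order
  manifest$used <- manifest$image_id %in% shown
  n_match <- as.integer(round(config$match_fraction * config$trials_per_block))
  cond <- unlist(lapply(seq_len(config$n_blocks), function(b)
    sample(rep(c("match", "mismatch"),
               c(n_match, config$trials_per_block - n_match)))))
  lp <- .lognormal_pars(config$rt_mean_s, config$rt_sd_s)
  rt <- stats::rlnorm(n_trials, lp$meanlog, lp$sdlog)
  timeout <- rt > 2
  resp <- sample(c("real", "fake"), n_trials, replace = TRUE)
  ai <- ifelse(cond == "match", resp,
               ifelse(resp == "real", "fake", "real"))
  resp[timeout] <- "timeout"
  ai[timeout] <- NA_character_
  trials <- data.frame(
    block = rep(seq_len(config$n_blocks), each = config$trials_per_block),
    index_in_block = rep(seq_len(config$trials_per_block), config$n_blocks),
    condition = cond,
    stimulus_id = shown,
    stimulus_class = manifest$class[match(shown, manifest$image_id)],
    participant_response = resp,
    ai_response = ai,
    reaction_time_s = pmin(rt, 2))
  structure(list(trials = trials, manifest = manifest, config = config),
            class = "woz_session")
}

#' @export
print.woz_session <- function(x, ...) {
  cat(sprintf("woz_session: %d trials in %d blocks (%d%% match), %d timeouts\n",
              nrow(x$trials), x$config$n_blocks,
              round(100 * x$config$match_fraction),
              sum(x$trials$participant_response == "timeout")))
  invisible(x)
}

#' Parameters of the damped-oscillation rating generator
#'
#' A parametric stand-in for the qualitative pattern seen in repeated
#' reliability ratings: early oscillation around an asymptote that dampens
#' as interactions accumulate.  The block-`b` rating is
#' `asymptote + (start - asymptote + A * cos(2*pi*b/period)) * exp(-damping*b)
#' + noise`, clipped to \[0, 100\].  This closed form is a generator device,
#' not a cognitive model.
#'
#' @param start_rating Initial rating level (percent, default 50).
#' @param asymptote Late-session rating level (default 75, the scripted
#'   agreement rate).
#' @param oscillation_amplitude Oscillation amplitude in percent (default 15).
#' @param oscillation_period_blocks Oscillation period in blocks (default 5).
#' @param damping_rate Exponential damping per block (default 0.15).
#' @param noise_sd Rating noise SD in percent (default 3).
#' @param seed Integer seed.
#' @return A `rating_params` object.
#' @export
rating_params <- function(start_rating = 50, asymptote = 75,
                          oscillation_amplitude = 15,
                          oscillation_period_blocks = 5,
                          damping_rate = 0.15, noise_sd = 3, seed = 1L) {
  vals <- c(start_rating, asymptote, oscillation_amplitude,
            oscillation_period_blocks, damping_rate, noise_sd)
  if (any(!is.finite(vals)) || oscillation_period_blocks <= 0 ||
      damping_rate < 0 || noise_sd < 0)
    stop("invalid rating generator parameters", call. = FALSE)
  structure(list(start_rating = start_rating, asymptote = asymptote,
                 oscillation_amplitude = oscillation_amplitude,
                 oscillation_period_blocks = oscillation_period_blocks,
                 damping_rate = damping_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "rating_params")
}

#' Deterministic part of the rating generator
#' @param params A [rating_params()].
#' @param b Block index (vectorised, >= 0).
#' @return Rating values before noise and clipping.
#' @export
rating_mean <- function(params, b) {
  with(params, asymptote +
    (start_rating - asymptote +
       oscillation_amplitude * cos(2 * pi * b / oscillation_period_blocks)) *
    exp(-damping_rate * b))
}

#' Generate a block-by-block reliability-rating trajectory
#'
#' One rating per block plus the pre-practice and post-practice ratings
#' (`n_blocks + 2` observations).  The pre-practice rating (block index -1,
#' before any interaction) is the start level plus noise; block indices
#' `0 ... n_blocks` follow the damped-cosine form of [rating_mean()], with
#' block 0 the post-practice rating.  All ratings are clipped to \[0, 100\]
#' and mapped to the 11-level state scale.
#'
#' @param params A [rating_params()].
#' @param n_blocks Number of experimental blocks (default 20).
#' @param space State space for the mapping.
#' @return Data frame with `block_index` (-1 .. n_blocks), `raw_rating`,
#'   `state`.
#' @export
generate_rating_trajectory <- function(params = rating_params(),
                                       n_blocks = 20L,
                                       space = state_space(11L)) {
  stopifnot(inherits(params, "rating_params"))
  set.seed(params$seed)
  b <- 0:n_blocks
  mu <- c(params$start_rating, rating_mean(params, b))
  r <- mu + stats::rnorm(length(mu), 0, params$noise_sd)
  r <- pmin(pmax(r, 0), 100)
  rating_observation(c(-1L, b), r, space)
}

#' Default EEG montage of the epoch generator
#'
#' A 16-channel subset of the extended 10-20 system covering the six
#' analysis regions.
#'
#' @return Character vector of channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F3", "Fz", "F4", "C3", "Cz", "C4",
    "T7", "T8", "P3", "Pz", "P4", "O1", "Oz", "O2")
}

#' Default per-condition ERP component template
#'
#' Emulates the reported feedback-locked morphology: an early visual
#' response over occipital channels in both conditions, a P3-like positive
#' component at 376 ms over central channels that is twice as large on
#' (rare) mismatch trials, and a small mismatch-only negativity at 268 ms.
#' Each component is a Gaussian bump `amplitude * exp(-(t - latency)^2 /
#' (2 * width^2))` added to every channel of its scalp region.
#'
#' @return List with `match` and `mismatch`, each a data frame of
#'   components (`latency_ms`, `width_ms`, `amplitude_uv`, `region`).
#' @export
default_erp_template <- function() {
  visual <- data.frame(latency_ms = 150, width_ms = 30, amplitude_uv = 3,
                       region = "occipital")
  list(
    match = rbind(visual,
                  data.frame(latency_ms = 376, width_ms = 50,
                             amplitude_uv = 4, region = "central")),
    mismatch = rbind(visual,
                     data.frame(latency_ms = 376, width_ms = 50,
                                amplitude_uv = 8, region = "central"),
                     data.frame(latency_ms = 268, width_ms = 25,
                                amplitude_uv = -3, region = "central")))
}

#' Generate synthetic event-locked EEG epochs for a session
#'
#' Builds one epoch per non-timeout trial (timeouts have no AI-feedback
#' event to lock to): the condition's template components, projected onto
#' their region's channels, plus white Gaussian noise.  Each trial also
#' gets a simulated event timeline — fixation of 0.6--1.0 s, image shown
#' until the reaction time, participant icon for 0.3 s, then the AI
#' feedback at time zero — from which the per-trial 600 ms baseline window
#' (the fixation period preceding image onset) is computed; when that
#' window would start before the epoch does, it is shifted right to the
#' epoch start.
#'
#' @param session A [generate_session()] result.
#' @param erp_template Per-condition component lists; see
#'   [default_erp_template()].
#' @param noise_sd_uv White-noise SD in microvolts (default 5).
#' @param sampling_rate Hz (default 250).
#' @param epoch_window `(start_ms, end_ms)` around the feedback event
#'   (default `c(-1300, 950)`).
#' @param channel_labels Montage (default [default_montage()]).
#' @param region_map Channel-region assignment (default
#'   [default_region_map()]).
#' @param seed Integer seed for the noise and event timing.
#' @return An [epoch_set()].
#' @export
generate_epochs <- function(session,
                            erp_template = default_erp_template(),
                            noise_sd_uv = 5, sampling_rate = 250,
                            epoch_window = c(-1300, 950),
                            channel_labels = default_montage(),
                            region_map = default_region_map(),
                            seed = 1L) {
  stopifnot(inherits(session, "woz_session"))
  comps <- rbind(erp_template$match, erp_template$mismatch)
  if (any(comps$latency_ms < epoch_window[1] |
          comps$latency_ms > epoch_window[2]))
    stop("template component latency outside the epoch window", call. = FALSE)
  unknown <- setdiff(unique(comps$region), names(region_map))
  if (length(unknown))
    stop("template regions not in the region map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!all(unlist(region_map[unique(comps$region)]) %in% channel_labels))
    stop("region map names channels missing from the montage", call. = FALSE)
  trials <- session$trials[session$trials$participant_response != "timeout", ,
                           drop = FALSE]
  n_tr <- nrow(trials)
  n_ch <- length(channel_labels)
  n_samp <- epoch_sample_count(epoch_window, sampling_rate)
  tt <- epoch_window[1] + (seq_len(n_samp) - 1L) * 1000 / sampling_rate
  # per-condition noiseless template, channels x samples
  condition_signal <- function(cond) {
    sig <- matrix(0, n_ch, n_samp, dimnames = list(channel_labels, NULL))
    tpl <- erp_template[[cond]]
    for (k in seq_len(nrow(tpl))) {
      bump <- tpl$amplitude_uv[k] *
        exp(-(tt - tpl$latency_ms[k])^2 / (2 * tpl$width_ms[k]^2))
      ch <- region_map[[tpl$region[k]]]
      sig[ch, ] <- sig[ch, , drop = FALSE] + rep(bump, each = length(ch))
    }
    sig
  }
  sig <- list(match = condition_signal("match"),
              mismatch = condition_signal("mismatch"))
  set.seed(seed)
  data <- array(0, c(n_ch, n_samp, n_tr))
  for (tr in seq_len(n_tr)) {
    data[, , tr] <- sig[[trials$condition[tr]]] +
      matrix(stats::rnorm(n_ch * n_samp, 0, noise_sd_uv), n_ch, n_samp)
  }
  fixation_s <- stats::runif(n_tr, 0.6, 1.0)
  image_onset_ms <- -(trials$reaction_time_s + 0.3) * 1000
  bl_start <- pmax(image_onset_ms - 600, epoch_window[1])
  bl_end <- bl_start + 600
  meta <- data.frame(condition = trials$condition,
                     reaction_time_s = trials$reaction_time_s,
                     response_given = TRUE,
                     baseline_start_ms = bl_start,
                     baseline_end_ms = bl_end,
                     fixation_s = fixation_s,
                     block = trials$block,
                     index_in_block = trials$index_in_block)
  epoch_set(data, sampling_rate, epoch_window, channel_labels, meta)
}
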