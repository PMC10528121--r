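#' Event-locked EEG epochs
#'
#' Container for already-cleaned epochs time-locked to the AI-feedback
#' event.  Samples lie on the grid `start_ms + k * 1000/sampling_rate`,
#' `k = 0 ... floor((end_ms - start_ms) * sampling_rate / 1000)`; at the
#' default window (-1300 ... +950 ms, 250 Hz) that is 563 samples from
#' -1300 to +948 ms.
#'
#' @param data Numeric array `channels x samples x trials`, in microvolts.
#' @param sampling_rate Sampling rate in Hz (default 250).
#' @param epoch_window Length-2 vector `(start_ms, end_ms)` relative to the
#'   feedback event (default `c(-1300, 950)`).
#' @param channel_labels Character vector of 10-20-system channel names.
#' @param trial_meta Data frame, one row per trial: `condition` ("match" or
#'   "mismatch"), `reaction_time_s`, `response_given` (logical),
#'   `baseline_start_ms`, `baseline_end_ms` (per-trial baseline window,
#'   inside the epoch window).
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, sampling_rate = 250,
                      epoch_window = c(-1300, 950),
                      channel_labels = NULL, trial_meta) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n_samp <- epoch_sample_count(epoch_window, sampling_rate)
  if (dim(data)[2] != n_samp)
    stop("data has ", dim(data)[2], " samples but the window implies ",
         n_samp, call. = FALSE)
  if (is.null(channel_labels))
    channel_labels <- paste0("Ch", seq_len(dim(data)[1]))
  if (dim(data)[1] != length(channel_labels))
    stop("channel_labels length does not match data", call. = FALSE)
  if (nrow(trial_meta) != dim(data)[3])
    stop("trial_meta rows do not match trial count", call. = FALSE)
  need <- c("condition", "reaction_time_s", "response_given",
            "baseline_start_ms", "baseline_end_ms")
  miss <- setdiff(need, names(trial_meta))
  if (length(miss))
    stop("trial_meta missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(trial_meta$condition %in% c("match", "mismatch")))
    stop("condition must be 'match' or 'mismatch'", call. = FALSE)
  bad <- trial_meta$baseline_start_ms < epoch_window[1] |
         trial_meta$baseline_end_ms > epoch_window[2] |
         trial_meta$baseline_end_ms <= trial_meta$baseline_start_ms
  if (any(bad))
    stop(sum(bad), " trial(s) have baseline windows outside the epoch",
         call. = FALSE)
  dimnames(data) <- list(channel_labels, NULL, NULL)
  structure(list(data = data, sampling_rate = sampling_rate,
                 epoch_window = as.numeric(epoch_window),
                 channel_labels = channel_labels,
                 trial_meta = as.data.frame(trial_meta)),
            class = "epoch_set")
}

#' Number of samples implied by an epoch window
#' @param epoch_window `(start_ms, end_ms)`.
#' @param sampling_rate Hz.
#' @return Integer sample count.
#' @export
epoch_sample_count <- function(epoch_window, sampling_rate) {
  as.integer(floor(diff(epoch_window) * sampling_rate / 1000 + 1e-9)) + 1L
}

#' Sample times of an epoch set
#' @param epochs An [epoch_set()].
#' @return Numeric vector of sample times in ms relative to the event.
#' @export
epoch_times <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs$epoch_window[1] +
    (seq_len(dim(epochs$data)[2]) - 1L) * 1000 / epochs$sampling_rate
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set: %d channels x %d samples x %d trials (%g Hz, %g..%g ms)\n",
              d[1], d[2], d[3], x$sampling_rate,
              x$epoch_window[1], x$epoch_window[2]))
  print(table(x$trial_meta$condition))
  invisible(x)
}

#' Reject artifact and timeout trials
#'
#' Removes trials whose voltage on any channel exceeds the artifact limit —
#' by default the peak-to-peak range within the epoch ("large voltage
#' changes"), optionally the absolute amplitude — and trials with a missing
#' or too-slow response (no key press within the response limit means no
#' feedback event occurred).  Surviving trials are returned untouched.
#'
#' @param epochs An [epoch_set()].
#' @param voltage_limit_uv Artifact threshold in microvolts (default 100).
#' @param rt_limit_s Response-time limit in seconds (default 2).
#' @param mode `"peak_to_peak"` (default) or `"absolute"`.
#' @return The filtered `epoch_set`, with attribute `"rejection_log"` (a
#'   data frame of trial index and reason).  Raises an error if every trial
#'   is rejected.
#' @export
reject_trials <- function(epochs, voltage_limit_uv = 100, rt_limit_s = 2,
                          mode = c("peak_to_peak", "absolute")) {
  stopifnot(inherits(epochs, "epoch_set"))
  mode <- match.arg(mode)
  if (voltage_limit_uv <= 0 || rt_limit_s <= 0)
    stop("rejection limits must be positive", call. = FALSE)
  n_tr <- dim(epochs$data)[3]
  volt_bad <- vapply(seq_len(n_tr), function(tr) {
    x <- matrix(epochs$data[, , tr], nrow = dim(epochs$data)[1])
    if (mode == "peak_to_peak") {
      rng <- apply(x, 1, function(v) diff(range(v)))
      any(rng > voltage_limit_uv)
    } else {
      max(abs(x)) > voltage_limit_uv
    }
  }, logical(1))
  rt_bad <- !epochs$trial_meta$response_given |
    epochs$trial_meta$reaction_time_s > rt_limit_s
  reason <- rep(NA_character_, n_tr)
  reason[rt_bad] <- "timeout"
  reason[volt_bad] <- ifelse(rt_bad[volt_bad], "voltage+timeout", "voltage")
  keep <- !(volt_bad | rt_bad)
  if (!any(keep))
    stop("all trials rejected; nothing left to average", call. = FALSE)
  out <- epochs
  out$data <- epochs$data[, , keep, drop = FALSE]
  out$trial_meta <- epochs$trial_meta[keep, , drop = FALSE]
  rownames(out$trial_meta) <- NULL
  attr(out, "rejection_log") <-
    data.frame(trial = which(!keep), reason = reason[!keep])
  out
}

#' Per-trial baseline correction
#'
#' Subtracts, for each trial and channel, the mean voltage over that
#' trial's own baseline window (600 ms of the fixation period preceding the
#' image stimulus, carried in `trial_meta`).  Idempotent: a second
#' application subtracts a zero mean.
#'
#' @param epochs An [epoch_set()].
#' @return The baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  tt <- epoch_times(epochs)
  out <- epochs
  for (tr in seq_len(dim(epochs$data)[3])) {
    sel <- tt >= epochs$trial_meta$baseline_start_ms[tr] &
           tt <= epochs$trial_meta$baseline_end_ms[tr]
    if (!any(sel))   # cannot happen for a valid epoch_set; defensive
      stop("trial ", tr, ": baseline window contains no samples",
           call. = FALSE)
    mu <- rowMeans(epochs$data[, sel, tr, drop = FALSE])
    out$data[, , tr] <- epochs$data[, , tr] - mu
  }
  out
}

#' Default scalp region map
#'
#' Editable assignment of 10-20 channels to the six analysis regions
#' (frontal, central, left/right temporal, parietal, occipital), matched to
#' the montage produced by [generate_epochs()].
#'
#' @return Named list of character vectors of channel labels.
#' @export
default_region_map <- function() {
  list(frontal        = c("Fp1", "Fp2", "F3", "Fz", "F4"),
       central        = c("C3", "Cz", "C4"),
       left_temporal  = c("T7"),
       right_temporal = c("T8"),
       parietal       = c("P3", "Pz", "P4"),
       occipital      = c("O1", "Oz", "O2"))
}

#' Condition-averaged ERPs, difference wave and region averages
#'
#' Averages epochs within each condition into per-channel ERP waveforms,
#' forms the difference wave (match minus mismatch), and averages member
#' channels within each scalp region, per condition and for the difference.
#'
#' @param epochs An [epoch_set()] (typically after [reject_trials()] and
#'   [baseline_correct()]).
#' @param region_map Named list of channel labels per region; see
#'   [default_region_map()].  Regions with no channel present in the data
#'   are dropped with a warning.
#' @return An `erp_result`: `erp_match`, `erp_mismatch`, `erp_difference`
#'   (channel x sample matrices, microvolts), `region_averages` (list with
#'   `match`, `mismatch`, `difference`; region x sample matrices), `times`,
#'   `n_trials_used`.
#' @export
average_by_condition <- function(epochs, region_map = default_region_map()) {
  stopifnot(inherits(epochs, "epoch_set"))
  cond <- epochs$trial_meta$condition
  n_used <- c(match = sum(cond == "match"), mismatch = sum(cond == "mismatch"))
  if (any(n_used == 0L))
    stop("condition with zero trials: ",
         paste(names(n_used)[n_used == 0L], collapse = ", "), call. = FALSE)
  avg <- function(which) {
    sel <- which(cond == which)
    m <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
    rownames(m) <- epochs$channel_labels
    m
  }
  em <- avg("match"); eu <- avg("mismatch")
  diffw <- em - eu
  region_map <- lapply(region_map, intersect, epochs$channel_labels)
  empty <- lengths(region_map) == 0L
  if (any(empty)) {
    warning("dropping regions with no channels in the data: ",
            paste(names(region_map)[empty], collapse = ", "))
    region_map <- region_map[!empty]
  }
  regionize <- function(m) {
    r <- t(vapply(region_map,
                  function(ch) colMeans(m[ch, , drop = FALSE]),
                  numeric(ncol(m))))
    rownames(r) <- names(region_map)
    r
  }
  structure(list(erp_match = em, erp_mismatch = eu, erp_difference = diffw,
                 region_averages = list(match = regionize(em),
                                        mismatch = regionize(eu),
                                        difference = regionize(diffw)),
                 times = epoch_times(epochs), n_trials_used = n_used),
            class = "erp_result")
}

#' Sample-aligned peak or trough latency
#'
#' Finds the extremum of a single waveform inside a latency window, at
#' sample resolution (no interpolation): positive polarity returns the
#' maximum, negative the minimum.
#'
#' @param waveform Numeric vector (one channel's or region's ERP,
#'   microvolts).
#' @param times Sample times in ms, same length as `waveform` (e.g.
#'   [epoch_times()] or an `erp_result`'s `times`).
#' @param search_window_ms Length-2 vector `(lo, hi)` in ms; must contain
#'   at least 3 samples.
#' @param polarity `"positive"` or `"negative"`.
#' @return List `latency_ms`, `amplitude_uv`, `flat` (TRUE when the window
#'   is constant, in which case the window start is returned).
#' @export
peak_latency <- function(waveform, times, search_window_ms,
                         polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(length(waveform) == length(times), length(search_window_ms) == 2L)
  sel <- which(times >= search_window_ms[1] & times <= search_window_ms[2])
  if (length(sel) < 3L)
    stop("search window must contain at least 3 samples", call. = FALSE)
  w <- waveform[sel]
  if (diff(range(w)) == 0)
    return(list(latency_ms = times[sel[1]], amplitude_uv = w[1], flat = TRUE))
  k <- if (polarity == "positive") which.max(w) else which.min(w)
  list(latency_ms = times[sel[k]], amplitude_uv = w[k], flat = FALSE)
}

#' Write epochs to a paired-CSV container
#'
#' Plain-text layout: `<stem>_meta.csv` holds one header row of container
#' fields (sampling rate, window, channel labels) followed by the trial
#' metadata table; `<stem>_data.csv` holds the flattened array, one row per
#' (trial, channel) with sample values in columns.
#'
#' @param epochs An [epoch_set()].
#' @param stem Output path stem (no extension).
#' @return `stem`, invisibly.
#' @export
write_epochs <- function(epochs, stem) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  header <- data.frame(sampling_rate = epochs$sampling_rate,
                       window_start_ms = epochs$epoch_window[1],
                       window_end_ms = epochs$epoch_window[2],
                       channels = paste(epochs$channel_labels, collapse = ";"))
  utils::write.csv(header, paste0(stem, "_header.csv"), row.names = FALSE)
  utils::write.csv(epochs$trial_meta, paste0(stem, "_meta.csv"),
                   row.names = FALSE)
  flat <- matrix(aperm(epochs$data, c(1, 3, 2)), d[1] * d[3], d[2])
  idx <- data.frame(trial = rep(seq_len(d[3]), each = d[1]),
                    channel = rep(epochs$channel_labels, d[3]))
  utils::write.csv(cbind(idx, as.data.frame(flat)),
                   paste0(stem, "_data.csv"), row.names = FALSE)
  invisible(stem)
}

#' Read epochs from a paired-CSV container
#' @param stem Path stem used with [write_epochs()].
#' @return An [epoch_set()].
#' @export
read_epochs <- function(stem) {
  hdr_path <- paste0(stem, "_header.csv")
  if (!file.exists(hdr_path))
    stop("epoch container not found: ", hdr_path, call. = FALSE)
  hdr <- utils::read.csv(hdr_path)
  meta <- utils::read.csv(paste0(stem, "_meta.csv"))
  raw <- utils::read.csv(paste0(stem, "_data.csv"))
  channels <- strsplit(hdr$channels, ";", fixed = TRUE)[[1]]
  n_ch <- length(channels); n_tr <- nrow(meta)
  vals <- as.matrix(raw[order(raw$trial, match(raw$channel, channels)),
                        -(1:2)])
  n_samp <- ncol(vals)
  data <- aperm(array(t(vals), c(n_samp, n_ch, n_tr)), c(2, 1, 3))
  epoch_set(data, hdr$sampling_rate,
            c(hdr$window_start_ms, hdr$window_end_ms), channels, meta)
}
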