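test_that("epoch geometry: default window at 250 Hz gives 563 samples on a 4 ms grid", {
  expect_identical(epoch_sample_count(c(-1300, 950), 250), 563L)
  ep <- toy_epochs(array(0, c(2, 563, 2)))
  tt <- epoch_times(ep)
  expect_equal(tt[1], -1300)
  expect_equal(tt[length(tt)], 948)
  expect_equal(unique(diff(tt)), 4)
  expect_error(epoch_set(array(0, c(2, 100, 2)), trial_meta = data.frame()),
               "samples")
})

test_that("voltage rejection removes large swings and keeps quiet trials", {
  n_s <- 563
  data <- array(stats::rnorm(3 * n_s * 5, 0, 2), c(3, n_s, 5))
  data[] <- pmin(pmax(data, -10), 10)          # everything within +/-10 uV
  data[2, 100, 2] <- 80; data[2, 101, 2] <- -80   # 160 uV swing, trial 2
  data[1, 300, 4] <- 120                           # 130-ish uV swing, trial 4
  ep <- toy_epochs(data)
  kept <- reject_trials(ep)
  expect_identical(dim(kept$data)[3], 3L)
  log <- attr(kept, "rejection_log")
  expect_setequal(log$trial, c(2L, 4L))
  expect_true(all(log$reason == "voltage"))
  # a single 150 uV swing on one channel is enough
  one <- array(0, c(3, n_s, 2)); one[3, 50, 1] <- 150
  kept1 <- reject_trials(toy_epochs(one))
  expect_identical(attr(kept1, "rejection_log")$trial, 1L)
  # nothing removed when all trials are quiet and fast
  quiet <- toy_epochs(array(stats::runif(3 * n_s * 4, -10, 10), c(3, n_s, 4)))
  expect_identical(dim(reject_trials(quiet)$data)[3], 4L)
})

test_that("timeout and missing-response trials are rejected", {
  data <- array(0, c(2, 563, 4))
  ep <- toy_epochs(data, rt = c(0.5, 2.4, 0.7, 1.1),
                   response_given = c(TRUE, TRUE, FALSE, TRUE))
  kept <- reject_trials(ep)
  expect_setequal(attr(kept, "rejection_log")$trial, c(2L, 3L))
  expect_true(all(attr(kept, "rejection_log")$reason == "timeout"))
  # rejecting everything is an explicit error
  expect_error(reject_trials(toy_epochs(data, rt = rep(3, 4))),
               "all trials rejected")
})

test_that("rejection is a pure filter on the surviving trials", {
  set.seed(5)
  data <- array(stats::rnorm(4 * 563 * 6, 0, 5), c(4, 563, 6))
  data[1, 10, 3] <- 500
  ep <- toy_epochs(data)
  kept <- reject_trials(ep)
  expect_equal(kept$data, ep$data[, , -3])
})

test_that("baseline correction subtracts each trial's own window mean and is idempotent", {
  n_s <- 563
  data <- array(0, c(2, n_s, 2))
  data[, , 1] <- 5                               # constant trial -> zeros
  tt <- -1300 + (0:562) * 4
  bump <- 6 * exp(-(tt - 400)^2 / (2 * 50^2))
  data[1, , 2] <- 2 + bump                       # offset + late bump
  ep <- toy_epochs(data)
  bc <- baseline_correct(ep)
  expect_equal(unname(bc$data[, , 1]), matrix(0, 2, n_s))
  sel <- tt >= -1300 & tt <= -700
  expect_equal(mean(bc$data[1, sel, 2]), 0, tolerance = 1e-9)
  expect_equal(bc$data[1, , 2], data[1, , 2] - mean(data[1, sel, 2]),
               tolerance = 1e-9)
  expect_equal(baseline_correct(bc)$data, bc$data, tolerance = 1e-12)
})

test_that("condition averages, difference wave and region means are exact", {
  n_s <- 563
  # 4 trials with constant known values: match 2 & 4, mismatch 1 & 7
  vals <- c(2, 1, 4, 7)
  cond <- c("match", "mismatch", "match", "mismatch")
  data <- array(0, c(3, n_s, 4))
  for (k in 1:4) data[, , k] <- vals[k]
  ep <- toy_epochs(data, condition = cond)
  rmap <- list(front = c("Fp1", "Fp2"), solo = "F3")
  erp <- average_by_condition(ep, rmap)
  expect_equal(unique(as.vector(erp$erp_match)), 3)       # (2+4)/2
  expect_equal(unique(as.vector(erp$erp_mismatch)), 4)    # (1+7)/2
  expect_equal(erp$erp_difference, erp$erp_match - erp$erp_mismatch)
  expect_equal(unique(as.vector(erp$region_averages$difference)), -1)
  expect_equal(erp$n_trials_used, c(match = 2L, mismatch = 2L))
  # mismatch = match + 3 uV -> difference identically -3
  d2 <- array(1, c(3, n_s, 4)); d2[, , cond == "mismatch"] <- 4
  e2 <- average_by_condition(toy_epochs(d2, condition = cond), rmap)
  expect_true(all(e2$erp_difference == -3))
  # identical conditions -> zero difference
  e3 <- average_by_condition(toy_epochs(array(2, c(3, n_s, 4)),
                                        condition = cond), rmap)
  expect_true(all(e3$erp_difference == 0))
  expect_error(average_by_condition(
    toy_epochs(data, condition = rep("match", 4)), rmap), "zero trials")
})

test_that("averaging is permutation-invariant and the pipeline is linear", {
  set.seed(9)
  data <- array(stats::rnorm(3 * 563 * 8), c(3, 563, 8))
  cond <- rep(c("match", "mismatch"), 4)
  ep <- toy_epochs(data, condition = cond)
  perm <- sample(8)
  epp <- toy_epochs(data[, , perm], condition = cond[perm])
  rmap <- list(a = c("Fp1", "F3"))
  expect_equal(average_by_condition(ep, rmap)$erp_difference,
               average_by_condition(epp, rmap)$erp_difference,
               tolerance = 1e-12)
  eps <- toy_epochs(3.5 * data, condition = cond)
  e1 <- average_by_condition(baseline_correct(ep), rmap)
  es <- average_by_condition(baseline_correct(eps), rmap)
  expect_equal(es$erp_difference, 3.5 * e1$erp_difference, tolerance = 1e-9)
  expect_equal(es$region_averages$match, 3.5 * e1$region_averages$match,
               tolerance = 1e-9)
})

test_that("peak detection is sample-aligned and polarity-aware", {
  tt <- -1300 + (0:562) * 4
  bump <- 5 * exp(-(tt - 376)^2 / (2 * 40^2))
  pk <- peak_latency(bump, tt, c(300, 500), "positive")
  expect_lte(abs(pk$latency_ms - 376), 4)
  expect_equal(pk$amplitude_uv, 5, tolerance = 1e-3)
  expect_false(pk$flat)
  neg <- peak_latency(-bump, tt, c(300, 500), "negative")
  expect_equal(neg$latency_ms, pk$latency_ms)
  ramp <- peak_latency(seq_along(tt) * 0.01, tt, c(300, 500), "positive")
  expect_equal(ramp$latency_ms, 500)
  flat <- peak_latency(rep(1, 563), tt, c(300, 500), "positive")
  expect_true(flat$flat)
  expect_equal(flat$latency_ms, 300)
  expect_error(peak_latency(bump, tt, c(300, 302), "positive"), "3 samples")
})

test_that("epochs survive a round trip through the paired-CSV container", {
  set.seed(31)
  data <- array(round(stats::rnorm(3 * 50 * 4, 0, 5), 4), c(3, 50, 4))
  ep <- toy_epochs(data, window = c(-100, 96))
  stem <- file.path(withr::local_tempdir(), "epochs")
  write_epochs(ep, stem)
  back <- read_epochs(stem)
  expect_equal(back$data, ep$data, tolerance = 1e-9,
               ignore_attr = "dimnames")
  expect_equal(back$trial_meta$condition, ep$trial_meta$condition)
  expect_equal(back$sampling_rate, ep$sampling_rate)
  expect_error(read_epochs(file.path(tempdir(), "missing_stem")),
               "not found")
})
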