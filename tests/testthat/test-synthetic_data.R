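test_that("the default session matches the study design exactly", {
  sess <- generate_session(session_config(seed = 2))
  tr <- sess$trials
  expect_identical(nrow(tr), 560L)
  per_block <- tapply(tr$condition == "match", tr$block, sum)
  expect_true(all(per_block == 21L))
  expect_true(all(tapply(tr$condition == "mismatch", tr$block, sum) == 7L))
  expect_identical(sum(sess$manifest$class == "fake"), 294L)
  expect_identical(sum(sess$manifest$class == "real"), 294L)
  # each image at most once, 50/50 presentation balance
  expect_false(any(duplicated(tr$stimulus_id)))
  expect_identical(sum(tr$stimulus_class == "real"), 280L)
  # condition definition: AI agrees on match, disagrees on mismatch
  ok <- tr$participant_response != "timeout"
  expect_true(all((tr$ai_response == tr$participant_response)[ok] ==
                    (tr$condition == "match")[ok]))
  expect_true(all(is.na(tr$ai_response[!ok])))
  expect_true(all(tr$reaction_time_s <= 2))
})

test_that("session generation is seed-deterministic and respects boundaries", {
  a <- generate_session(session_config(seed = 77))
  b <- generate_session(session_config(seed = 77))
  expect_identical(a, b)
  c <- generate_session(session_config(seed = 78))
  expect_false(identical(a$trials$condition, c$trials$condition))
  all_match <- generate_session(session_config(match_fraction = 1, seed = 1))
  expect_true(all(all_match$trials$condition == "match"))
  expect_error(session_config(match_fraction = 0.9, trials_per_block = 28),
               "integer")
  expect_error(generate_session(
    session_config(n_real_images = 10, n_fake_images = 10)), "manifest")
})

test_that("the rating trajectory follows the damped cosine exactly without noise", {
  p <- rating_params(start_rating = 40, asymptote = 70,
                     oscillation_amplitude = 10,
                     oscillation_period_blocks = 5,
                     damping_rate = 0.2, noise_sd = 0, seed = 1)
  r <- generate_rating_trajectory(p, 20)
  expect_identical(nrow(r), 22L)                 # n_blocks + 2 observations
  expect_identical(r$block_index, c(-1L, 0:20))
  b <- 0:20
  expected <- 70 + (40 - 70 + 10 * cos(2 * pi * b / 5)) * exp(-0.2 * b)
  expect_equal(r$raw_rating[r$block_index >= 0], expected, tolerance = 1e-12)
  expect_equal(r$raw_rating[r$block_index == -1], 40)
  # heavy damping pins everything past block 0 to the asymptote
  pd <- rating_params(start_rating = 20, asymptote = 60, damping_rate = 50,
                      noise_sd = 0)
  rd <- generate_rating_trajectory(pd, 10)
  expect_equal(rd$raw_rating[rd$block_index >= 1], rep(60, 10),
               tolerance = 1e-6)
  # ratings always stay on the slider scale
  ph <- rating_params(start_rating = 95, asymptote = 98,
                      oscillation_amplitude = 40, noise_sd = 10, seed = 3)
  expect_true(all(generate_rating_trajectory(ph, 20)$raw_rating <= 100))
})

test_that("least-squares refits recover the generator's asymptote and damping", {
  # 50-replicate simulation study at the generator defaults: the asymptote
  # is sharply identified (median relative error ~1.3%); the damping rate,
  # entering only through the decaying envelope of 21 noisy points, carries
  # a median relative error of ~12.4% under these conditions, which is the
  # bound frozen here.
  truth <- rating_params()
  rel_err <- t(vapply(1:50, function(sd) {
    p <- truth; p$seed <- 1000L + sd
    r <- generate_rating_trajectory(p, 20)
    r <- r[r$block_index >= 0, ]
    fit <- stats::optim(c(asym = 60, damp = 0.3), function(th) {
      q <- truth; q$asymptote <- th[1]; q$damping_rate <- th[2]
      sum((r$raw_rating - rating_mean(q, r$block_index))^2)
    }, control = list(reltol = 1e-10, maxit = 2000))
    abs(fit$par - c(truth$asymptote, truth$damping_rate)) /
      c(truth$asymptote, truth$damping_rate)
  }, numeric(2)))
  expect_lt(stats::median(rel_err[, 1]), 0.10)
  expect_lt(stats::median(rel_err[, 2]), 0.13)
})

test_that("noiseless epochs reproduce the template bump exactly", {
  sess <- generate_session(session_config(n_blocks = 1, trials_per_block = 8,
                                          rt_mean_s = 0.5, rt_sd_s = 0.1,
                                          seed = 5))
  tpl <- list(match = data.frame(latency_ms = 376, width_ms = 50,
                                 amplitude_uv = 8, region = "central"),
              mismatch = data.frame(latency_ms = 376, width_ms = 50,
                                    amplitude_uv = 8, region = "central"))
  ep <- generate_epochs(sess, erp_template = tpl, noise_sd_uv = 0, seed = 1)
  tt <- epoch_times(ep)
  for (tr in seq_len(dim(ep$data)[3])) {
    cz <- ep$data["Cz", , tr]
    expect_equal(max(cz), 8, tolerance = 1e-9)
    expect_equal(tt[which.max(cz)], 376)
    expect_equal(unique(ep$data["O1", , tr]), 0)   # outside the region
  }
})

test_that("averaging noisy epochs converges to the template (law of large numbers)", {
  sess <- generate_session(session_config(n_blocks = 25, trials_per_block = 8,
                                          match_fraction = 1,
                                          rt_mean_s = 0.5, rt_sd_s = 0.05,
                                          seed = 6))
  tpl <- list(match = data.frame(latency_ms = 376, width_ms = 50,
                                 amplitude_uv = 8, region = "central"),
              mismatch = data.frame(latency_ms = 376, width_ms = 50,
                                    amplitude_uv = 8, region = "central"))
  noise_sd <- 4
  ep <- generate_epochs(sess, erp_template = tpl, noise_sd_uv = noise_sd,
                        seed = 2)
  n_tr <- dim(ep$data)[3]
  expect_gte(n_tr, 195)                      # ~200 trials, minus timeouts
  tt <- epoch_times(ep)
  template <- 8 * exp(-(tt - 376)^2 / (2 * 50^2))
  mean_cz <- rowMeans(ep$data["Cz", , ])
  expect_lt(max(abs(mean_cz - template)), 3 * noise_sd / sqrt(n_tr) *
              sqrt(2 * log(length(tt))))     # pointwise LLN with union slack
  expect_true(mean(abs(mean_cz - template) < 3 * noise_sd / sqrt(n_tr)) >
                0.99)
})

test_that("epoch generation is seed-deterministic and skips timeouts", {
  sc <- session_config(n_blocks = 2, trials_per_block = 8,
                       rt_mean_s = 1.2, rt_sd_s = 0.8, seed = 42)
  sess <- generate_session(sc)
  n_timeout <- sum(sess$trials$participant_response == "timeout")
  expect_gt(n_timeout, 0)                   # slow RT regime produces timeouts
  a <- generate_epochs(sess, noise_sd_uv = 2, seed = 9)
  b <- generate_epochs(sess, noise_sd_uv = 2, seed = 9)
  expect_identical(a, b)
  expect_identical(dim(a$data)[3], nrow(sess$trials) - n_timeout)
  # baseline windows are inside the epoch even for slow responses
  expect_true(all(a$trial_meta$baseline_start_ms >= a$epoch_window[1]))
  expect_true(all(a$trial_meta$baseline_end_ms <= a$epoch_window[2]))
})

test_that("template validation rejects impossible configurations", {
  sess <- generate_session(session_config(n_blocks = 1, trials_per_block = 4,
                                          seed = 3))
  bad_lat <- list(match = data.frame(latency_ms = 2000, width_ms = 50,
                                     amplitude_uv = 1, region = "central"),
                  mismatch = data.frame(latency_ms = 376, width_ms = 50,
                                        amplitude_uv = 1, region = "central"))
  expect_error(generate_epochs(sess, erp_template = bad_lat), "latency")
  bad_reg <- list(match = data.frame(latency_ms = 300, width_ms = 50,
                                     amplitude_uv = 1, region = "nowhere"),
                  mismatch = data.frame(latency_ms = 300, width_ms = 50,
                                        amplitude_uv = 1, region = "central"))
  expect_error(generate_epochs(sess, erp_template = bad_reg), "region")
})

test_that("the pipeline recovers the generated condition difference end to end", {
  sess <- generate_session(session_config(n_blocks = 4, trials_per_block = 28,
                                          rt_mean_s = 0.6, rt_sd_s = 0.15,
                                          seed = 10))
  ep <- generate_epochs(sess, noise_sd_uv = 5, seed = 11)
  erp <- average_by_condition(baseline_correct(reject_trials(ep)))
  tt <- erp$times
  win <- tt >= 300 & tt <= 500
  pk_match <- max(erp$region_averages$match["central", win])
  pk_mismatch <- max(erp$region_averages$mismatch["central", win])
  expect_gt(pk_mismatch, pk_match)
})
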