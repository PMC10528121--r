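#!/usr/bin/env Rscript
# Step 1: simulate the Wizard-of-Oz session that the downstream analyses
# consume — 20 blocks x 28 trials of real/fake face classification with
# scripted 75% AI agreement, plus the block-by-block reliability ratings
# (damped early oscillation towards the scripted agreement rate).
#
# Writes: results/trials.csv, results/manifest.csv, results/ratings.csv
# The EEG epochs are large and are generated on the fly by step 3.

library(reliwalk)

dir.create("results", showWarnings = FALSE)

sc <- session_config(seed = 20260101L)
session <- generate_session(sc)
write.csv(session$trials, "results/trials.csv", row.names = FALSE)
write.csv(session$manifest, "results/manifest.csv", row.names = FALSE)

ratings <- generate_rating_trajectory(rating_params(seed = 20260102L),
                                      sc$n_blocks)
write_ratings(ratings, "results/ratings.csv")

n_timeout <- sum(session$trials$participant_response == "timeout")
cat(sprintf(
  "Simulated %d trials in %d blocks (%d match / %d mismatch per block), %d timeouts.\n",
  nrow(session$trials), sc$n_blocks,
  round(sc$match_fraction * sc$trials_per_block),
  round((1 - sc$match_fraction) * sc$trials_per_block), n_timeout))
cat(sprintf(
  "Ratings: pre-practice %.1f%%, post-practice %.1f%% (start state %d), final block %.1f%%.\n",
  ratings$raw_rating[ratings$block_index == -1],
  ratings$raw_rating[ratings$block_index == 0],
  ratings$state[ratings$block_index == 0],
  ratings$raw_rating[ratings$block_index == sc$n_blocks]))
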