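#!/usr/bin/env Rscript

# Step 5: replay the online neurofeedback chain.
#
# Streams a simulated responder and a superficial-false-positive subject
# through the causal online chain (Beer-Lambert per sample, causal
# Butterworth 0.01-0.2 Hz, 2 s moving average, per-trial 5 s baseline,
# tanh gauge) and writes the per-sample feedback log. The correlation of
# the online signal with the neural ground truth, and its positive shift
# for the superficial subject, illustrate what the participant's gauge
# did and did not reflect.

suppressMessages(library(nirsfeed))

dir.create("results", showWarnings = FALSE)
resp <- simulate_cohort(1, "responder", sim_config(seed = 20260923L))[[1]]
fp <- simulate_cohort(1, "scalp_false_positive", sim_config(seed = 20260924L))[[1]]

logs <- list()
for (case in list(list(id = "responder", s = resp),
                  list(id = "scalp_false_positive", s = fp))) {
  out <- online_replay(case$s$recording)
  out$subject <- case$id
  logs[[case$id]] <- out
  neural <- case$s$truth$neural_hbo["S1-D1", ]
  sel <- out$phase != "baseline"
  task <- out$phase == "task"
  message(sprintf(
    "%s: cor(feedback, neural) = %.2f; mean feedback during task = %+.3f uM",
    case$id,
    if (stats::sd(neural[sel]) > 0) stats::cor(out$v[sel], neural[sel]) else NA,
    mean(out$v[task])))
}
gauge <- do.call(rbind, logs)
write.csv(gauge, "results/online_gauge_log.csv", row.names = FALSE)
message("wrote results/online_gauge_log.csv")
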