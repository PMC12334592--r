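#!/usr/bin/env Rscript
# Calibrate the chromatin-pioneering model against the cohort's
# condition-average trajectories (training: control, 1x6, 1x30, 4x1.5 --
# the canonical training quartet) by repeated particle-swarm optimization,
# then score the best replicate on the three post-hoc criteria.
# Replicates here are desk-scale (see the methods vignette); raise
# N_REPLICATES for production fits.

library(nfkbpulse)

N_REPLICATES <- 3
seed <- 2026

cohort <- read_cohort_csv("results/cohort.csv")
avg <- condition_averages(cohort)
train <- avg[c("control", "1x6", "1x30", "4x1.5")]
validation <- avg[c("1x15", "2x3", "3x2")]

base <- cohort$ground_truth
free <- c("ka", "ka1d", "kdNFKB", "Ps", "KDNA", "ka2a", "kd1d")
cal <- calibrate(train, base, free_names = free, n_replicates = N_REPLICATES,
                 seed = seed, swarm_size = 100, stall_iterations = 20,
                 max_iter = 300)
print(cal)

best <- cal$replicates[[cal$ranking[1]]]
crit <- evaluate_criteria(best$params, train, validation,
                          split_cohort(cohort))
cat(sprintf("best replicate: J = %.4g, emergent-property score = %.3f, <train SSE> = %.4g, validation SSE = %.4g\n",
            best$value, crit$ep_score, crit$mean_train_sse,
            crit$validation_sse))

out <- list(
  seed = seed, free_names = free,
  bounds = as.data.frame(t(cal$bounds)),
  replicates = lapply(cal$replicates, function(r)
    list(value = r$value, par_log10 = as.list(r$par))),
  best_params = unclass(best$params),
  criteria = crit)
jsonlite::write_json(out, "results/calibration.json", auto_unbox = TRUE,
                     digits = NA)
cat("wrote results/calibration.json\n")
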