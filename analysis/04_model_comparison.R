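#!/usr/bin/env Rscript
# Architecture comparison: does reproducing the pulse-train amplification
# require the DNA-binding/pioneering mechanism? Calibrates the base model
# (no DNA binding) and the two alternative-inhibitor variants on the same
# training data and compares emergent-property scores against the
# chromatin-pioneering model's best replicate.

library(nfkbpulse)

N_REPLICATES <- 2
seed <- 2026

cohort <- read_cohort_csv("results/cohort.csv")
avg <- condition_averages(cohort)
train <- avg[c("control", "1x6", "1x30", "4x1.5")]
cells <- split_cohort(cohort)

ep_for <- function(params, variant) {
  sim_aucs <- list(); exp_aucs <- list()
  for (cond in c("1x6", "1x15", "4x1.5")) {
    res <- simulate_cells(params, cells[[cond]]$ci, variant = variant)
    sim_aucs[[cond]] <- res$aucs[is.finite(res$aucs)]
    exp_aucs[[cond]] <- vapply(cells[[cond]]$nfkb, auc_fold_change, numeric(1))
  }
  emergent_property_score(sim_aucs, exp_aucs)
}

free_sets <- list(
  d2fc2 = c("ka", "ka1d", "kdNFKB", "Ps", "KDNA", "ka2a", "kd1d"),
  d2fc = c("ka", "kc", "ktr", "kdeg_t", "kimpN", "kb", "ka20"),
  d2fc_ikbe = c("ka", "kc", "ktr", "ktr_e", "ktl_e", "kimpIe", "ka20"),
  d2fc_ikbb = c("ka", "kc", "ktr", "ksyn_b", "ktl", "kimpIb", "ka20"))

rows <- list()
for (variant in names(free_sets)) {
  base <- default_parameters(variant)
  for (nm in names(base)) base[[nm]] <- cohort$ground_truth[[nm]]
  cal <- calibrate(train, base, free_names = free_sets[[variant]],
                   variant = variant, n_replicates = N_REPLICATES,
                   seed = seed, swarm_size = 100, stall_iterations = 20,
                   max_iter = 300)
  for (r in seq_along(cal$replicates)) {
    rep <- cal$replicates[[r]]
    rows[[length(rows) + 1]] <- data.frame(
      variant = variant, replicate = r, J = rep$value,
      ep_score = ep_for(rep$params, variant))
  }
  cat(sprintf("%-10s best J = %.4g\n", variant,
              min(vapply(cal$replicates, `[[`, numeric(1), "value"))))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/model_comparison.csv", row.names = FALSE)
print(aggregate(cbind(J, ep_score) ~ variant, tab, min), digits = 4)
cat("wrote results/model_comparison.csv\n")
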