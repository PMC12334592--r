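#!/usr/bin/env Rscript
# FRAP demonstration on synthetic recovery data: two stimulation regimes
# differing in the DNA-immobilized NF-kB fraction (modest after a single
# short pulse, larger after a pulse train). Simulates raw bleach/reference
# traces with acquisition photofading and noise, double-normalizes, fits
# the two-component recovery, and reports immobile fractions.

library(nfkbpulse)

dir.create("results", showWarnings = FALSE)
regimes <- list(
  `1x6`   = list(immobile = 0.15, n = 10),
  `4x1.5` = list(immobile = 0.40, n = 10))

rows <- list()
for (cond in names(regimes)) {
  rg <- regimes[[cond]]
  for (i in seq_len(rg$n)) {
    mobile <- 1 - rg$immobile
    a1 <- mobile * 0.45
    sim <- simulate_frap(y0 = mobile * 0.25, A1 = a1, tau1 = runif(1, 1.5, 3),
                         A2 = mobile - mobile * 0.25 - a1,
                         tau2 = runif(1, 12, 25),
                         fade_rate = 5e-4, noise_sd = 0.015,
                         seed = 100 * i + match(cond, names(regimes)))
    curve <- double_normalize(sim$raw_roi, sim$whole_ref, sim$n_prebleach,
                              times = sim$times)
    fit <- fit_recovery(curve)
    imm <- immobile_fraction(fit, curve$prebleach_mean)
    rows[[length(rows) + 1]] <- data.frame(
      condition = cond, cell = i, y0 = fit$y0, A1 = fit$A1, tau1 = fit$tau1,
      A2 = fit$A2, tau2 = fit$tau2, plateau = fit$plateau,
      immobile_fraction = imm$fraction, immobile_total = imm$total)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/frap_fits.csv", row.names = FALSE)

cat("Median immobile fraction by condition (truth: 0.15 vs 0.40):\n")
print(round(tapply(tab$immobile_fraction, tab$condition, median), 3))
tst <- t.test(immobile_fraction ~ condition, tab)
cat(sprintf("Welch t-test 1x6 vs 4x1.5: p = %.2g\n", tst$p.value))
cat("wrote results/frap_fits.csv\n")
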