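#!/usr/bin/env Rscript
# Mechanistic demonstration of co-antioxidant synergy.
#
# In the persistent-phenoxyl regime (self-decay dominates over rare
# phenoxyl-peroxyl cross-termination), a weak co-antioxidant that shows no
# induction period of its own prolongs the induction period of the lead
# chain-breaker when regeneration operates at k_r >= 2k_TO; with k_r = 0
# the mixture is simply additive.

library(autoxkin)

dir.create("results", showWarnings = FALSE)

run_tau <- function(k_r, roster, t_end) {
  d <- synergy_demo(k_r = k_r)
  d$system$antioxidants <- d$system$antioxidants[roster]
  tr <- generate_trace(d$system, d$params,
                       noise = noise_model(sigma = 0, seed = 1),
                       t_end = t_end)
  estimate_tau(tr, n_boot = 0)
}

lead <- run_tau(0, 1, 4000)
co <- run_tau(0, 2, 4000)
mix0 <- run_tau(0, 1:2, 4000)
mixR <- run_tau(2e3, 1:2, 6000)

out <- data.frame(
  run = c("lead alone", "co alone", "mixture k_r = 0",
          "mixture k_r = 2e3"),
  tau_s = c(lead$tau, 0, mix0$tau, mixR$tau),
  tau_over_sum = c(NA, NA, mix0$tau / lead$tau, mixR$tau / lead$tau))
write.csv(out, "results/synergy.csv", row.names = FALSE)

cat("Synergy demonstration (liposome-like, 1 uM each):\n")
print(out, row.names = FALSE, digits = 4)
cat(sprintf(paste0("\nWithout regeneration the mixture is additive ",
                   "(%.1f%% of the sum); with k_r >= 2k_TO the induction ",
                   "period exceeds the sum by %.0f%%.\n"),
            100 * mix0$tau / lead$tau, 100 * (mixR$tau / lead$tau - 1)))
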