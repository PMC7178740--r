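#!/usr/bin/env Rscript
# Noise arm of the Monte-Carlo study: additive Gaussian measurement noise
# N(0, epsilon^2) is layered on both groups at fixed n = 30 per group, and
# the rejection rate of every index is tracked as epsilon grows. Under the
# null the indices are essentially immune to noise — it only inflates the
# common variance — while under a true effect the standardized effect
# shrinks (delta_eps = delta / sqrt(1 + 2 eps^2 / (s1^2 + s2^2))) and all
# indices lose sensitivity. Desk scale: epsilon in {1, 3, 5}, 500
# replicates; the published study uses 0.5-5 in steps of 0.5 at 10,000.
#
# Writes: results/rates_by_noise.csv (+ manifest), per-setting pivots

library(btindices)

dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(
  settings = builtin_settings()[c("null", "large")],
  n_grid = integer(0),
  epsilon_grid = c(1, 3, 5),
  noise_n = 30L,
  priors = list(prior_spec("wide")),
  reps = 500L,
  base_seed = 2026L
)

rates <- run_grid(cfg, progress = TRUE)
write_rates(rates, "results/rates_by_noise.csv",
            manifest = run_manifest(cfg, rates))

report <- summarize_rates(rates, arm = "epsilon")
for (setting in names(report)) {
  cat("\n== ", setting, " effect: proportion significant by noise SD ==\n",
      sep = "")
  print(as.data.frame(report[[setting]]), digits = 3)
  readr::write_csv(report[[setting]],
                   sprintf("results/rates_by_noise_%s.csv", setting))
}

large <- report$large
bf <- unlist(large[large$index == "bf10", -1])
cat(sprintf("\n- large effect, BF10: %.2f at eps=1 down to %.2f at eps=5\n",
            bf[1], bf[length(bf)]))
cat("  (true |delta| shrinks from 1.03 to",
    sprintf("%.2f as noise dilutes the group separation)\n",
            1.03 / sqrt(1 + 2 * 25 / (3.4^2 + 5.8^2))))
cat("wrote results/rates_by_noise.csv and per-setting pivots\n")
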