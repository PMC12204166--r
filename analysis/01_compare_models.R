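#!/usr/bin/env Rscript
# Elastic vs plastic elongation under the same constant traction.
#
# Simulates the Kelvin-Voigt and ratchet-polymerization models with the
# control tissue constants (rest 20 um, elastic amplitude 40 um, tau 5 min,
# plastic rate 0.2 um/min), both starting unstretched. The two curves share
# the initial elastic step; the elastic material then plateaus at 60 um
# while the plastic one keeps elongating at 0.2 um/min.

suppressPackageStartupMessages(library(epirheo))

res <- compare_models(t_max = 300, dt = 0.5, out_dir = "results")

cat("Late-slope summary (window 100-300 min):\n")
print(res$summary)
kv <- subset(res$summary, model == "KELVIN_VOIGT")
ra <- subset(res$summary, model == "RATCHET")
cat(sprintf(
  "\nThe elastic model plateaus (late slope %.4f um/min, asymptote %.0f um);\n",
  kv$late_slope_um_per_min, kv$asymptote_um))
cat(sprintf(
  "the plastic model keeps elongating at %.4f um/min. Only the plastic\n",
  ra$late_slope_um_per_min))
cat("material can sustain the hours-long linear elongation of dorsal closure.\n")
cat("\nWrote results/compare_models_trajectories.csv and *_summary.json\n")
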