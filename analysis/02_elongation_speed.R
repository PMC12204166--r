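#!/usr/bin/env Rscript
# Tissue elongation trajectories and per-embryo speeds.
#
# Generates synthetic control and tkv embryos over a 150-min closure
# (control: ratchet, onset 60 um; tkv: pure Kelvin-Voigt, already
# equilibrated) with the default measurement noise and inter-embryo
# variability, then fits one linear regression per embryo — the standard
# elongation-speed readout.

suppressPackageStartupMessages(library(epirheo))

seed <- 20260901L
spec <- experiment_spec(n = 9, sampling_interval = 1, duration = 150,
                        seed = seed)
dir.create("results", showWarnings = FALSE)

speeds <- list()
for (genotype in c("control", "tkv")) {
  traj <- simulate_trajectories(spec, make_preset(genotype, "tissue"))
  write_trajectory_csv(traj,
                       file.path("results",
                                 paste0("trajectories_", genotype, ".csv")))
  sp <- elongation_speed(traj)
  sp$genotype <- genotype
  speeds[[genotype]] <- sp
}
speeds <- do.call(rbind, speeds)
readr::write_csv(speeds, "results/elongation_speeds.csv")

cat("Per-embryo elongation speeds (um/min):\n")
print(aggregate(speed_um_per_min ~ genotype, speeds,
                function(x) c(mean = mean(x), sd = sd(x))))
cat(sprintf(
  "\nControl embryos elongate at ~%.2f um/min (60 -> 90 um over 150 min);\n",
  mean(speeds$speed_um_per_min[speeds$genotype == "control"])))
cat(sprintf(
  "tkv embryos, lacking the plastic ratchet, stay flat (%.3f um/min).\n",
  mean(speeds$speed_um_per_min[speeds$genotype == "tkv"])))
cat("Wrote results/trajectories_{control,tkv}.csv, results/elongation_speeds.csv\n")
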