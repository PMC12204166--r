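#!/usr/bin/env Rscript
# Synthetic laser-ablation experiments and material-class discrimination.
#
# For each cell-scale preset (control ratchet, tkv Kelvin-Voigt, Maxwell
# alternative): simulate 30 ablated cells, fit the exponential recoil of
# each retraction curve (recovering tau and the ablation proxies), and run
# the recoil-ratio-versus-length regression that separates the three
# material classes.

suppressPackageStartupMessages(library(epirheo))

seed <- 20260902L
dir.create("results", showWarnings = FALSE)

rows <- list()
for (genotype in c("control", "tkv", "maxwell_demo")) {
  spec <- experiment_spec(n = 30, sampling_interval = 0.25, duration = 30,
                          seed = seed + match(genotype,
                                              c("control", "tkv",
                                                "maxwell_demo")))
  abl <- simulate_ablation(spec, make_preset(genotype, "cell"))
  readr::write_csv(abl$records,
                   file.path("results",
                             paste0("recoil_records_", genotype, ".csv")))
  fits <- lapply(split(abl$curves, abl$curves$cell_id),
                 fit_exponential_recoil)
  taus <- vapply(fits, `[[`, numeric(1), "tau_fit")
  res <- discriminate_records(
    abl$records,
    out = file.path("results",
                    paste0("discrimination_", genotype, ".json")))
  cat(sprintf("\n== %s ==\n", genotype))
  print(res)
  cat(sprintf("mean fitted retraction time: %.2f min (true 5 min)\n",
              mean(taus)))
  rows[[genotype]] <- tibble::tibble(
    genotype = genotype, classification = res$classification,
    slope_per_um = res$slope, p_value = res$p_value,
    mean_ratio = res$mean_ratio, mean_tau_fit = mean(taus))
}
readr::write_csv(do.call(rbind, rows), "results/discrimination_summary.csv")

cat("\nControl cells keep a length-independent ~25% recoil ratio (ratchet\n")
cat("plasticity); tkv cells show a rising ratio (Kelvin-Voigt elasticity);\n")
cat("the Maxwell alternative shows a falling ratio. Reports in results/.\n")
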