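#!/usr/bin/env Rscript
# Simulate the reference panel of single wells: a monomer control, a
# one-state well, a continuous low-to-high well, and a discontinuous well
# with and without its seed. Writes event tables and the ground truth under
# results/wells/.

suppressPackageStartupMessages(library(damfretr))
seed <- 1L
outdir <- "results/wells"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

panel <- list(
  control = phenotype_spec("one_state_low"),
  one_state_low = phenotype_spec("one_state_low"),
  continuous = phenotype_spec("continuous_low_to_high", true_c50 = 100,
                              true_amp = 0.3, true_a = 2),
  discontinuous = phenotype_spec("discontinuous", true_c50 = 200,
                                 true_amp = 0.35),
  discontinuous_seeded = phenotype_spec("discontinuous", true_c50 = 200,
                                        true_amp = 0.35, seeded = TRUE,
                                        seed_fold_reduction = 4))

truth <- lapply(panel, unclass)
jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
for (nm in names(panel)) {
  ev <- simulate_events(panel[[nm]], 1e5, rng_seed = seed + match(nm, names(panel)))
  write_well_csv(ev, file.path(outdir, paste0(nm, ".csv")))
  cat(sprintf("%-22s %6d events  (behavior %s, seeded %s)\n", nm, nrow(ev),
              panel[[nm]]$behavior, panel[[nm]]$seeded))
}
cat("wells written to", outdir, "\n")
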