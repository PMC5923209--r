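#!/usr/bin/env Rscript
# Stage 1: synthesize the phantom cohort and quantify HAT on both paths.
#
# Seven control-like and eight ischemic-like left-ventricle phantoms are
# generated with Rician noise (sigma/S0 = 0.02). Each is analysed twice:
# from its simulated 12-direction DWI stack (log-linear tensor fit ->
# helix angle -> 20-ray transmurality) and from its simulated optical
# volume (stripe filter -> 3D structure tensor -> helix angle ->
# downsample -> transmurality). Per-phantom results go to
# results/phantom_study.tsv.
#
# Finding (seed 1): recovered |HAT| group means are ~1.31 (control) vs
# ~0.79 deg/%TD (ischemic) by DTI, matching the generative design, and
# the two paths agree per phantom to a few hundredths of a deg/%TD.

suppressPackageStartupMessages(library(cardiohelix))

seed <- 1
dir.create("results", showWarnings = FALSE)

study <- run_phantom_study(n_control = 7, n_ischemic = 8, seed = seed,
                           noise_sigma = 0.02, optical = TRUE)
write.table(study, "results/phantom_study.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Per-phantom HAT (deg/%TD):\n")
print(study, digits = 4)
cat(sprintf("\nGroup means |HAT| (DTI):     control %.3f, ischemic %.3f\n",
            mean(study$abs_dti[study$group == "control"]),
            mean(study$abs_dti[study$group == "ischemic"])))
cat(sprintf("Group means |HAT| (optical): control %.3f, ischemic %.3f\n",
            mean(study$abs_opt[study$group == "control"]),
            mean(study$abs_opt[study$group == "ischemic"])))
cat("\nWrote results/phantom_study.tsv\n")
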