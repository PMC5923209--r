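#!/usr/bin/env Rscript
# Stage 4: regional and infarct-zone analysis on a lesion phantom.
#
# One ischemic-like phantom (60-degree infarct sector with elevated MD
# and flattened helix angle, plus a peri-infarct ring) is analysed on the
# DTI path. The mean-diffusivity map is zoned with the standard
# thresholds (infarct > 1.12, peri-infarct 0.9-1.12, remote <= 0.9
# um^2/ms), profile slopes are binned into the AHA 16-segment model
# (infarcted segments omitted) and into 100 radial segments of 3.6
# degrees, and peri-infarct vs remote HAT is compared with a paired
# per-slice t-test. Writes results/aha16.tsv, results/radial_segments.tsv
# and results/region_hat.tsv.
#
# Finding (seed 11): zoning matches the generative labels at ~100% of
# myocardial voxels; segments covering the lesion sector are omitted;
# peri-infarct |HAT| is clearly below remote |HAT|.

suppressPackageStartupMessages(library(cardiohelix))

dir.create("results", showWarnings = FALSE)
spec <- phantom_spec(dim = c(64, 64, 16), ha_endo = 60, ha_epi = -60,
                     lesion = lesion_spec(azimuth = 45),
                     noise = list(type = "rician", sigma = 0.02),
                     seed = 11)
fib <- make_fiber_field(make_lv_geometry(spec))
dti <- analyze_dwi_path(synthesize_dwi(fib))

acc <- mean(dti$labels[fib$mask & dti$mask] ==
              fib$truth$labels[fib$mask & dti$mask])
cat(sprintf("MD zoning agreement with ground truth: %.1f%%\n", 100 * acc))

seg <- aha16_bin(dti$hat$fits)
write.table(seg, "results/aha16.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("\nAHA 16-segment HAT (NA = omitted infarct segment):\n")
print(seg, digits = 3, row.names = FALSE)

rad <- radial_segment_bin(dti$hat$fits)
write.table(rad, "results/radial_segments.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("\nRadial segments: %d of 100 bins filled\n",
            sum(!is.na(rad$hat))))

rh <- dti$region_hat
write.table(rh, "results/region_hat.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("\nZone HAT (deg/%TD):\n")
print(rh, digits = 3, row.names = FALSE)

# paired per-slice comparison of peri-infarct vs remote slopes
fits <- dti$hat$fits
fits <- fits[is.finite(fits$slope) & !(fits$infarct %in% TRUE), ]
per_slice <- function(code) {
  tapply(fits$slope[fits$region == code], fits$slice[fits$region == code],
         mean)
}
peri <- per_slice(2L); remote <- per_slice(1L)
common <- intersect(names(peri), names(remote))
if (length(common) >= 3) {
  p <- t.test(peri[common], remote[common], paired = TRUE)$p.value
  cat(sprintf("\nPaired t-test peri-infarct vs remote slope: p = %.3g\n", p))
}
cat("\nWrote results/aha16.tsv, results/radial_segments.tsv, results/region_hat.tsv\n")
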