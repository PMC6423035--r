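#!/usr/bin/env Rscript
# Step 1 — generate the default synthetic nest phantom (seed 42) and record
# its ground truth: dimensions, closed-pore census, and the anchor-to-rim
# profiles that characterize the graded architecture.

suppressPackageStartupMessages(library(nestmech))
dir.create("results", showWarnings = FALSE)

bundle <- generate_phantom(phantom_params(seed = 42L))
print(bundle)

s <- spacing_mm(bundle$material_truth)
idx <- which(bundle$material_truth$data)
co <- arrayInd(idx, dim(bundle$material_truth$data))
cat(sprintf("extents (mm): U-D %.1f, B-F %.1f, R-L %.1f\n",
            diff(range(co[, 1])) * s + s, diff(range(co[, 2])) * s + s,
            diff(range(co[, 3])) * s + s))

summ <- summarize_nest(bundle$material_truth, bundle$pore_truth,
                       mass = bundle$params$target_mass)
print(summ)

prof <- ground_truth_profiles(bundle, "BF")
utils::write.csv(prof, "results/01_truth_profile_bf.csv", row.names = FALSE)

po <- pore_orientation(bundle$pore_truth)
utils::write.csv(po, "results/01_truth_pores.csv", row.names = FALSE)
cat(sprintf("pores: %d, median elongation %.2f, median angle to R-L %.1f deg\n",
            nrow(po), stats::median(po$elongation[!po$degenerate]),
            stats::median(po$angle_rl, na.rm = TRUE)))

# archive the phantom image as a TIFF stack with sidecar metadata
dir.create("results/phantom_stack", showWarnings = FALSE)
write_volume(bundle$image, "results/phantom_stack", "tiff_stack")
cat("wrote results/01_truth_profile_bf.csv, results/01_truth_pores.csv, results/phantom_stack/\n")
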