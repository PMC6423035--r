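#!/usr/bin/env Rscript
# Step 4 — tensile data reduction. No measured force-displacement records are
# distributed with the package, so a synthetic cohort is drawn from the
# published material statistics (peak stress 2.75 +/- 0.79 MPa, modulus
# 155 MPa, strain to fracture ~0.125) and pushed through the full reduction:
# engineering stress-strain, modulus fit, failure detection, aggregation by
# cut orientation.

suppressPackageStartupMessages(library(nestmech))
dir.create("results", showWarnings = FALSE)

records <- simulate_tensile_cohort(n = 30, mean_sigma_f = 2.75,
                                   sd_sigma_f = 0.79, E_mean = 155,
                                   eps_fail = 0.125, seed = 7L)
# archive the cohort in the canonical CSV layout
df <- do.call(rbind, lapply(records, function(r)
  data.frame(specimen_id = r$specimen_id, force_N = r$force,
             displacement_um = r$displacement, A0_mm2 = r$A0, L0_mm = r$L0,
             cut_angle_deg = r$cut_angle)))
utils::write.csv(df, "results/04_tensile_records.csv", row.names = FALSE)

curves <- lapply(read_tensile_csv("results/04_tensile_records.csv"),
                 to_stress_strain)
per <- do.call(rbind, lapply(curves, function(cu)
  data.frame(specimen_id = cu$specimen_id, cut_angle = cu$cut_angle,
             E_mpa = cu$E, sigma_peak_mpa = cu$sigma_peak,
             eps_fracture = cu$eps_fracture,
             n_drops = nrow(cu$drop_events))))
utils::write.csv(per, "results/04_per_specimen.csv", row.names = FALSE)

agg <- aggregate_curves(curves)
print(agg)
print(agg$by_orientation, row.names = FALSE)
utils::write.csv(agg$by_orientation, "results/04_by_orientation.csv",
                 row.names = FALSE)
cat(sprintf("cohort: sigma_f %.2f +/- %.2f MPa, E %.0f MPa, median eps_fracture %.3f\n",
            agg$mean_sigma_f, agg$sd_sigma_f, agg$mean_E,
            stats::median(per$eps_fracture)))
cat("wrote results/04_*.csv\n")
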