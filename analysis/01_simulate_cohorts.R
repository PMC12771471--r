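#!/usr/bin/env Rscript
# Simulate the study cohorts: a control (GFP RNAi) cohort with the natural
# sexual dimorphism (female spot radii 1.3x male), and a dsx-knockdown
# cohort in which that female enlargement is abolished (female_scale = 1),
# emulating the loss of dimorphism after dsx RNAi. Images go to scratch/
# (binary), ground truth to results/ (text).

suppressPackageStartupMessages(library(elytramorph))

dir.create("results", showWarnings = FALSE)
dir.create("scratch/images", showWarnings = FALSE, recursive = TRUE)

n_per_sex <- 10

control <- render_cohort(n_per_sex, female_scale = 1.3, seed = 20011)
knockdown <- render_cohort(n_per_sex, female_scale = 1.0, seed = 20012)

truth_records <- function(cohort, treatment) {
  do.call(rbind, lapply(cohort, function(e) {
    data.frame(individual_id = paste0(treatment, "_", e$individual_id),
               sex = toupper(substr(e$sex, 1, 1)), treatment = treatment,
               spot_index = 1:10,
               true_normalized_area =
                 as.numeric(e$truth$spot_areas) / e$truth$wing_area)
  }))
}

truth <- rbind(truth_records(control, "GFP_RNAi"),
               truth_records(knockdown, "dsx_RNAi"))
write_tsv(truth, "results/ground_truth_areas.tsv")

for (e in c(control, knockdown)) {
  trt <- if (e$config$female_scale > 1) "GFP_RNAi" else "dsx_RNAi"
  write_image_png(e$image, file.path("scratch/images",
                  paste0(trt, "_", e$individual_id, ".png")))
}

agg <- aggregate(true_normalized_area ~ sex + treatment, truth, mean)
cat("Simulated", 2 * n_per_sex, "elytra per treatment.\n")
cat("Mean true normalized spot area by group:\n")
print(agg, row.names = FALSE)
cat("\nControl F/M area ratio:",
    round(agg$true_normalized_area[agg$sex == "F" &
            agg$treatment == "GFP_RNAi"] /
          agg$true_normalized_area[agg$sex == "M" &
            agg$treatment == "GFP_RNAi"], 3),
    "(expected ~1.69 = 1.3^2)\n")
cat("Knockdown F/M area ratio:",
    round(agg$true_normalized_area[agg$sex == "F" &
            agg$treatment == "dsx_RNAi"] /
          agg$true_normalized_area[agg$sex == "M" &
            agg$treatment == "dsx_RNAi"], 3), "(expected ~1)\n")
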