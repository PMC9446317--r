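#!/usr/bin/env Rscript
# Stage 1: simulate the imaging cohort.
#
# Generates 60 subjects: multi-component lesion masks (1-4 spherical
# blobs, radii 3-6 mm, per-subject dispersion 5-18 mm), noisy ADC maps
# (lesion 400e-6, background 800e-6, noise 25e-6 mm^2/s), clinical
# covariates, and an AF outcome following a logistic model on age, sex
# and lesion multifocality. One shared toy atlas provides hemisphere /
# territory / cortical labels. Everything is written under
# results/study/ as NIfTI + CSV so later stages rely only on files.

suppressPackageStartupMessages(library(lesionshape))

seed <- 42
n_subjects <- 60
out <- "results/study"
dir.create(file.path(out, "adc"), recursive = TRUE, showWarnings = FALSE)

study <- simulate_study(n_subjects, seed = seed)

for (sub in study$subjects) {
  write_volume_nifti(sub$adc, file.path(out, "adc", paste0(sub$id, ".nii.gz")))
}
write_volume_nifti(study$atlas, file.path(out, "atlas.nii.gz"))
write.csv(study$atlas$label_table, file.path(out, "atlas_labels.csv"),
          row.names = FALSE)
write.csv(study$clinical, file.path(out, "clinical.csv"), row.names = FALSE)

gt <- lapply(study$subjects, function(s)
  list(id = s$id, n_components = s$ground_truth$n_components,
       component_volumes_mm3 = s$ground_truth$component_volumes_mm3))
jsonlite::write_json(list(seed = seed, n_subjects = n_subjects,
                          ground_truth = gt),
                     file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("Simulated %d subjects (seed %d): %d with AF (%.0f%%), %d ADC volumes under %s\n",
            n_subjects, seed, sum(study$clinical$af),
            100 * mean(study$clinical$af), n_subjects, out))
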