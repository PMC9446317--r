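#!/usr/bin/env Rscript
# Stage 3: lesion location by atlas overlap.
#
# Classifies each segmented mask against the toy atlas: affected
# hemisphere (left/right/both), vascular territory (left ICA / right ICA
# / basilar / multiple), and cortical involvement, each requiring at
# least 100 overlapping lesion voxels; lesions that nowhere reach the
# threshold keep their argmax class but are flagged.

suppressPackageStartupMessages(library(lesionshape))

study_dir <- "results/study"
atlas_raw <- read_volume_nifti(file.path(study_dir, "atlas.nii.gz"),
                               as = "atlas_labels")
atlas <- atlas_volume(atlas_raw$labels, atlas_raw$spacing_mm,
                      read.csv(file.path(study_dir, "atlas_labels.csv")))

mask_files <- list.files(file.path(study_dir, "masks"), full.names = TRUE)
rows <- lapply(mask_files, function(f) {
  id <- sub("\\.nii\\.gz$", "", basename(f))
  p <- locate_lesion(read_volume_nifti(f, as = "mask"), atlas,
                     min_voxels = 100)
  data.frame(id = id, hemisphere = p$hemisphere, territory = p$territory,
             cortical_involved = as.integer(p$cortical_involved),
             multiple_territories = as.integer(p$territory == "multiple"),
             bilateral = as.integer(p$hemisphere == "both"),
             location_below_threshold = as.integer(p$below_threshold))
})
loc <- do.call(rbind, rows)
write.csv(loc, "results/location.csv", row.names = FALSE)

cat(sprintf("Located %d lesions -> results/location.csv\n", nrow(loc)))
cat(sprintf("Multiple territories: %d (%.0f%%); bilateral: %d (%.0f%%); cortical: %d (%.0f%%); below threshold: %d\n",
            sum(loc$multiple_territories), 100 * mean(loc$multiple_territories),
            sum(loc$bilateral), 100 * mean(loc$bilateral),
            sum(loc$cortical_involved), 100 * mean(loc$cortical_involved),
            sum(loc$location_below_threshold)))
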