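#' Segment an acute ischemic lesion by ADC thresholding
#'
#' Acutely ischemic tissue shows restricted diffusion, i.e. low apparent
#' diffusion coefficient. A voxel is labelled lesion when it lies inside
#' the brain mask, its ADC value does not exceed the threshold (the upper
#' bound is inclusive), and its ADC value is strictly positive --
#' non-positive values are treated as invalid background so masking
#' artifacts cannot enter the lesion.
#'
#' @param adc an [image_volume()] ADC map in mm^2/s.
#' @param brain_mask a [lesion_mask()] delimiting brain tissue, same grid.
#' @param threshold upper ADC bound in mm^2/s; default 620e-6.
#' @return A [lesion_mask()] of the segmented lesion.
#' @export
segment_adc <- function(adc, brain_mask, threshold = 620e-6) {
  stopifnot(inherits(adc, "image_volume"), inherits(brain_mask, "lesion_mask"))
  check_same_grid(adc, brain_mask, "ADC and brain mask")
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0) {
    stopf("threshold must be a single positive number")
  }
  seg <- brain_mask$data == 1L & adc$data <= threshold & adc$data > 0
  lesion_mask(seg, adc$spacing_mm)
}

#' Remove implausibly small lesion components
#'
#' Drops every connected component whose physical volume is strictly
#' smaller than `min_volume_mm3`; a component of exactly that volume is
#' retained. Components are defined under the same connectivity as the
#' shape descriptors (26 by default) so the size filter and the component
#' count never disagree.
#'
#' @param mask a [lesion_mask()].
#' @param min_volume_mm3 minimum component volume in mm^3; default 10.
#' @param connectivity voxel adjacency, one of 6, 18, 26.
#' @return A [lesion_mask()] containing only the surviving components.
#' @export
remove_small_components <- function(mask, min_volume_mm3 = 10,
                                    connectivity = 26) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (min_volume_mm3 < 0) stopf("min_volume_mm3 must be >= 0")
  if (!any(mask$data == 1L)) return(mask)
  lab <- label_components(mask, connectivity = connectivity)
  keep <- which(lab$component_volumes_mm3 >= min_volume_mm3)
  out <- array(lab$labels %in% keep, dim(mask$data))
  lesion_mask(out, mask$spacing_mm)
}

#' Accept an externally edited lesion mask
#'
#' Hook for rater-corrected masks: validates that the edited mask is
#' binary and grid-consistent with the automatic segmentation, then
#' returns it verbatim with a provenance attribute recording how many
#' voxels were added and removed relative to the input.
#'
#' @param mask the automatic [lesion_mask()].
#' @param edits the manually corrected mask, same grid.
#' @return The edits as a [lesion_mask()], with attribute `provenance`.
#' @export
apply_manual_edits <- function(mask, edits) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (!inherits(edits, "lesion_mask")) {
    stopf("edits must be a lesion_mask (binary)")
  }
  check_same_grid(mask, edits, "mask and edits")
  out <- lesion_mask(edits$data, edits$spacing_mm)
  attr(out, "provenance") <- list(
    added = sum(edits$data == 1L & mask$data == 0L),
    removed = sum(edits$data == 0L & mask$data == 1L)
  )
  out
}
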