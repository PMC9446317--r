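#' Per-label overlap counts between a lesion and an atlas
#'
#' Counts, for every atlas label, how many lesion voxels fall on it. The
#' mask must already be in the atlas grid (registration is an input
#' contract, not a computation).
#'
#' @param mask a [lesion_mask()] in atlas space.
#' @param atlas an [atlas_volume()] on the same grid.
#' @return Named integer vector: label id -> lesion voxel count (all table
#'   labels present, zeros included).
#' @export
overlap_counts <- function(mask, atlas) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(atlas, "atlas_volume"))
  check_same_grid(mask, atlas, "mask and atlas")
  ids <- sort(atlas$label_table$label)
  hits <- atlas$labels[mask$data == 1L]
  hits <- hits[hits != 0L]
  counts <- vapply(ids, function(l) sum(hits == l), integer(1))
  names(counts) <- ids
  counts
}

#' Classify lesion location from atlas overlap
#'
#' Aggregates overlap counts to three class families -- hemisphere
#' (left/right), vascular territory (left ICA / right ICA / basilar), and
#' cortical involvement -- and calls a class affected when its aggregated
#' lesion overlap reaches `min_voxels` (default 100). Hemisphere is
#' `both` when both sides are affected; territory is `multiple` when two
#' or more territories are affected. If no hemisphere or no territory
#' reaches the threshold the class with maximal overlap is assigned and
#' the profile is flagged `below_threshold` so such subjects can be
#' excluded downstream.
#'
#' @param counts named vector from [overlap_counts()].
#' @param atlas the [atlas_volume()] the counts were computed against.
#' @param min_voxels minimum aggregated lesion voxels for a class to count
#'   as affected.
#' @return A list of class `location_profile`: `hemisphere`, `territory`,
#'   `cortical_involved`, `below_threshold`, `overlap_counts`.
#' @export
classify_location <- function(counts, atlas, min_voxels = 100) {
  stopifnot(inherits(atlas, "atlas_volume"))
  if (min_voxels < 0) stopf("min_voxels must be >= 0")
  tab <- atlas$label_table
  counts <- counts[match(tab$label, as.integer(names(counts)))]
  counts[is.na(counts)] <- 0L
  if (sum(counts) == 0) {
    stopf("lesion does not overlap any atlas label (no lesion in atlas space)")
  }

  agg <- function(keep) sum(counts[keep])
  hemi_counts <- c(left = agg(tab$hemisphere == "left"),
                   right = agg(tab$hemisphere == "right"))
  terr_counts <- c("left ICA" = agg(tab$territory == "left ICA"),
                   "right ICA" = agg(tab$territory == "right ICA"),
                   basilar = agg(tab$territory == "basilar"))
  cortical_count <- agg(tab$cortical)

  below <- FALSE
  hemi_hit <- names(hemi_counts)[hemi_counts >= min_voxels]
  if (length(hemi_hit) == 2L) hemisphere <- "both"
  else if (length(hemi_hit) == 1L) hemisphere <- hemi_hit
  else {
    hemisphere <- names(which.max(hemi_counts))
    below <- TRUE
  }

  terr_hit <- names(terr_counts)[terr_counts >= min_voxels]
  if (length(terr_hit) >= 2L) territory <- "multiple"
  else if (length(terr_hit) == 1L) territory <- terr_hit
  else {
    territory <- names(which.max(terr_counts))
    below <- TRUE
  }

  structure(list(hemisphere = hemisphere, territory = territory,
                 cortical_involved = cortical_count >= min_voxels,
                 below_threshold = below, overlap_counts = counts),
            class = "location_profile")
}

#' One-call location profile for a mask
#'
#' @param mask a [lesion_mask()] in atlas space.
#' @param atlas an [atlas_volume()].
#' @param min_voxels threshold passed to [classify_location()].
#' @return A `location_profile`, see [classify_location()].
#' @export
locate_lesion <- function(mask, atlas, min_voxels = 100) {
  classify_location(overlap_counts(mask, atlas), atlas, min_voxels)
}

#' @export
print.location_profile <- function(x, ...) {
  cat(sprintf("<location_profile> hemisphere=%s territory=%s cortical=%s%s\n",
              x$hemisphere, x$territory, x$cortical_involved,
              if (x$below_threshold) " (below threshold)" else ""))
  invisible(x)
}
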