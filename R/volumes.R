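#' Image volume: a 3D scalar grid with physical voxel spacing
#'
#' Lightweight carrier for ADC maps and other scalar volumes. Values are
#' stored as a numeric 3D array; `spacing_mm` gives the per-axis voxel edge
#' length in millimetres, so one voxel occupies `prod(spacing_mm)` mm^3.
#'
#' @param data 3D numeric array of finite values.
#' @param spacing_mm numeric length-3 vector of positive voxel sizes (mm).
#' @param units optional unit string for the scalar (e.g. "mm^2/s" for ADC).
#' @return An object of class `image_volume` with fields `data`,
#'   `spacing_mm`, `units`.
#' @export
image_volume <- function(data, spacing_mm, units = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stopf("image volume must be a 3D array")
  if (!all(is.finite(data))) stopf("image volume contains non-finite values")
  spacing_mm <- check_spacing(spacing_mm)
  structure(list(data = data, spacing_mm = spacing_mm, units = units),
            class = "image_volume")
}

#' Binary lesion mask
#'
#' @param data 3D array of 0/1 (or logical) values.
#' @param spacing_mm numeric length-3 vector of positive voxel sizes (mm).
#' @return An object of class `lesion_mask` with an integer 0/1 `data` array
#'   and `spacing_mm`.
#' @export
lesion_mask <- function(data, spacing_mm) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stopf("lesion mask must be a 3D array")
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
  } else {
    if (!all(data %in% c(0, 1))) stopf("lesion mask values must be 0 or 1")
    storage.mode(data) <- "integer"
  }
  spacing_mm <- check_spacing(spacing_mm)
  structure(list(data = data, spacing_mm = spacing_mm), class = "lesion_mask")
}

#' Atlas label volume with a label table
#'
#' The label table declares, for every non-zero label id, its anatomical
#' name, hemisphere (`left`/`right`/`none`), vascular territory
#' (`left ICA`/`right ICA`/`basilar`/`none`) and whether it is cortical.
#'
#' @param labels 3D integer array of label ids (0 = background).
#' @param spacing_mm numeric length-3 vector of positive voxel sizes (mm).
#' @param label_table data.frame with columns `label`, `name`, `hemisphere`,
#'   `territory`, `cortical`.
#' @return An object of class `atlas_volume`.
#' @export
atlas_volume <- function(labels, spacing_mm, label_table) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stopf("atlas must be a 3D array")
  storage.mode(labels) <- "integer"
  spacing_mm <- check_spacing(spacing_mm)
  need <- c("label", "name", "hemisphere", "territory", "cortical")
  if (!all(need %in% names(label_table))) {
    stopf("label_table must have columns: %s", paste(need, collapse = ", "))
  }
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, label_table$label)
  if (length(missing)) {
    stopf("labels present in volume but absent from table: %s",
          paste(missing, collapse = ", "))
  }
  structure(list(labels = labels, spacing_mm = spacing_mm,
                 label_table = label_table),
            class = "atlas_volume")
}

check_spacing <- function(spacing_mm) {
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || !all(is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stopf("spacing_mm must be 3 positive finite values")
  }
  spacing_mm
}

voxel_volume_mm3 <- function(x) prod(x$spacing_mm)

check_same_grid <- function(a, b, what = "volumes") {
  da <- dim(if (!is.null(a$data)) a$data else a$labels)
  db <- dim(if (!is.null(b$data)) b$data else b$labels)
  if (!identical(da, db)) stopf("%s have mismatched grid shapes", what)
  if (max(abs(a$spacing_mm - b$spacing_mm)) > 1e-6) {
    stopf("%s have mismatched voxel spacing", what)
  }
  invisible(TRUE)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm%s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              if (is.null(x$units)) "" else paste0(", units ", x$units)))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(signif(x$spacing_mm, 4), collapse = "x")))
  invisible(x)
}

#' Write a volume, mask or atlas to NIfTI
#'
#' @param x an `image_volume`, `lesion_mask` or `atlas_volume`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  arr <- if (!is.null(x$data)) x$data else x$labels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as an image volume or lesion mask
#'
#' Voxel spacing is taken from the NIfTI header (`pixdim`).
#'
#' @param path NIfTI file path.
#' @param as one of "image" (scalar volume), "mask" (binarised at > 0),
#'   or "atlas_labels" (integer label array; pair with a label table via
#'   [atlas_volume()]).
#' @return An `image_volume`, a `lesion_mask`, or (for "atlas_labels") a
#'   list with `labels` and `spacing_mm`.
#' @export
read_volume_nifti <- function(path, as = c("image", "mask", "atlas_labels")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  arr <- array(as.vector(as.array(img)), dim = dim(img))
  switch(as,
    image = image_volume(arr, spacing),
    mask = lesion_mask(arr > 0, spacing),
    atlas_labels = list(labels = array(as.integer(round(arr)), dim(arr)),
                        spacing_mm = as.numeric(spacing))
  )
}
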