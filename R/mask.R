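# Binary volume masks: the geometric object all morphometrics consume.

#' Create a binary volume mask
#'
#' A `volume_mask` wraps a 3D occupancy grid together with its voxel spacing
#' (edge lengths in mm) and a region label. Coordinates are 1-based voxel
#' indices at voxel centers, matching the native array order of the stored
#' grid.
#'
#' @param grid 3D array coercible to logical; `TRUE`/nonzero marks foreground.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param label region name, one of `"whole"`, `"head"`, `"body"`, `"tail"`.
#' @return an object of class `volume_mask`.
#' @export
volume_mask <- function(grid, spacing = c(1, 1, 1), label = "whole") {
  if (length(dim(grid)) != 3L) stop_input("mask grid must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_input("spacing must be 3 strictly positive voxel edge lengths (mm)")
  label <- match.arg(label, c("whole", "head", "body", "tail"))
  g <- array(grid != 0, dim = dim(grid))
  structure(list(grid = g, spacing = spacing, label = label),
            class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  cat(sprintf("<volume_mask '%s'> %s voxels, grid %s, spacing %s mm\n",
              x$label, sum(x$grid), paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

# Foreground voxel centers as an n x 3 matrix of 1-based indices.
mask_coords <- function(mask) {
  w <- which(mask$grid, arr.ind = TRUE)
  if (nrow(w) == 0L)
    stop_input("empty region: mask '%s' has no foreground voxels", mask$label)
  storage.mode(w) <- "double"
  dimnames(w) <- NULL
  w
}

#' Read labeled pancreas masks from a NIfTI file
#'
#' Expects integer labels 0 (background), 1 (head), 2 (body), 3 (tail); the
#' whole pancreas is the union of labels 1-3. Voxel spacing is taken from the
#' NIfTI header.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return named list of `volume_mask` objects: `whole`, `head`, `body`,
#'   `tail`.
#' @export
read_pancreas_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop_input("%s: expected a 3D label volume, got %d dims", path, length(dim(arr)))
  spacing <- RNifti::pixdim(img)[1:3]
  labs <- sort(unique(as.vector(arr)))
  if (!all(labs %in% 0:3))
    stop_input("%s: labels must be in {0,1,2,3}, found %s", path,
               paste(labs, collapse = ","))
  list(whole = volume_mask(arr >= 1 & arr <= 3, spacing, "whole"),
       head  = volume_mask(arr == 1, spacing, "head"),
       body  = volume_mask(arr == 2, spacing, "body"),
       tail  = volume_mask(arr == 3, spacing, "tail"))
}

#' Write a labeled pancreas mask to NIfTI
#'
#' @param labels 3D integer array with labels 0-3.
#' @param spacing voxel edge lengths in mm.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_pancreas_mask <- function(labels, spacing, path) {
  img <- RNifti::asNifti(array(as.integer(labels), dim = dim(labels)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
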