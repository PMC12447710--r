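#' Construct a volumetric image
#'
#' The image currency of the pipeline: a 3-D scalar field with voxel
#' spacing in mm, a physical origin, and a modality tag. Axis order is
#' (x, y, z) with x fastest-varying, matching the on-disk NIfTI layout after
#' reorientation to the canonical RAS-closest orientation.
#'
#' @param data 3-D numeric array.
#' @param spacing Numeric length-3, voxel spacing in mm (all > 0).
#' @param origin Numeric length-3, physical position of the first voxel (mm).
#' @param modality Modality tag (see \code{\link{magic_modalities}}).
#' @return An object of class \code{volume}.
#' @export
as_volume <- function(data, spacing, origin = c(0, 0, 0), modality = "SIM_CT") {
  if (length(dim(data)) != 3L)
    stop("expected 3-D volume, got ", length(dim(data)), " axes")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin), modality = modality),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("volume: %s, %s voxels @ %s mm, range [%.3g, %.3g]\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Read a 3-D NIfTI volume
#'
#' Reads a NIfTI-1 image, reorients it to the closest-to-RAS orientation so
#' that augmentation axes are reproducible, and extracts spacing and origin
#' from the header. The modality is supplied by the caller (usually from a
#' manifest), never guessed from the header.
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @param modality Modality tag to attach.
#' @return A \code{\link{as_volume}} object.
#' @export
read_volume <- function(path, modality = "SIM_CT") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected 3-D volume, got ", length(dim(img)), " axes in ", path)
  if (!is.na(RNifti::orientation(img)) && RNifti::orientation(img) != "RAS")
    RNifti::orientation(img) <- "RAS"
  d <- dim(img)
  hdr <- RNifti::niftiHeader(img)
  spacing <- as.numeric(hdr$pixdim[2:4])
  if (any(spacing <= 0)) stop("non-positive voxel spacing in ", path)
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  as_volume(array(as.numeric(img), d), spacing, origin, modality)
}

#' Write a volume to NIfTI
#' @param vol A \code{volume}.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  xf <- diag(4)
  diag(xf)[1:3] <- vol$spacing
  xf[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
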