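#' Composite segmentation: 20 binary masks that may overlap across groups
#'
#' A composite label holds one binary mask per catalog structure, all on one
#' grid. Structures from different groups may overlap (a voxel may be both
#' whole-heart and left atrium and mitral valve), but masks within one group
#' must be pairwise disjoint — each group is a single-label problem for its
#' decoder. Disjointness is validated at construction; violation is an
#' error, not a warning.
#'
#' @param masks Named list of logical 3-D arrays, one per catalog structure.
#' @param spacing Voxel spacing (mm).
#' @param catalog A \code{\link{structure_catalog}}.
#' @param origin Physical origin (mm).
#' @return An object of class \code{composite_segmentation}.
#' @export
composite_segmentation <- function(masks, spacing, catalog = structure_catalog(),
                                   origin = c(0, 0, 0)) {
  want <- catalog_structures(catalog)
  if (!setequal(names(masks), want))
    stop("masks must cover the full catalog; missing: ",
         paste(setdiff(want, names(masks)), collapse = ", "))
  masks <- masks[want]
  dims <- dim(masks[[1]])
  if (length(dims) != 3L) stop("masks must be 3-D")
  for (nm in want) {
    if (!identical(dim(masks[[nm]]), dims))
      stop("mask grids differ: ", nm)
    if (!is.logical(masks[[nm]])) masks[[nm]] <- array(masks[[nm]] != 0, dims)
  }
  x <- structure(list(masks = masks, spacing = as.numeric(spacing),
                      origin = as.numeric(origin), catalog = catalog),
                 class = "composite_segmentation")
  check_within_group_disjoint(x)
  x
}

check_within_group_disjoint <- function(composite) {
  for (g in names(composite$catalog$groups)) {
    nm <- composite$catalog$groups[[g]]
    if (length(nm) < 2) next
    count <- Reduce(`+`, lapply(composite$masks[nm], function(m) m + 0L))
    if (any(count > 1L))
      stop("within-group overlap in group ", g, " (",
           sum(count > 1L), " voxels carry two labels)")
  }
  invisible(TRUE)
}

#' @export
print.composite_segmentation <- function(x, ...) {
  nv <- vapply(x$masks, sum, numeric(1))
  cat(sprintf("composite segmentation: %s grid @ %s mm, %d/%d non-empty masks\n",
              paste(dim(x$masks[[1]]), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(nv > 0), length(nv)))
  invisible(x)
}

#' Integer label map of one structure group
#'
#' The decoder-facing representation of one non-overlapping group:
#' 0 is background, k the k-th structure of the group in catalog order.
#'
#' @param labels Integer 3-D array.
#' @param group_id Group id (e.g. "A".."D").
#' @param catalog A \code{\link{structure_catalog}}.
#' @param spacing Voxel spacing (mm).
#' @return An object of class \code{group_label_map}.
#' @export
group_label_map <- function(labels, group_id, catalog = structure_catalog(),
                            spacing = c(1, 1, 1)) {
  if (!group_id %in% names(catalog$groups)) stop("unknown group: ", group_id)
  n <- length(catalog$groups[[group_id]])
  if (any(labels < 0L | labels > n))
    stop("label values outside [0, ", n, "] for group ", group_id)
  structure(list(labels = labels, group_id = group_id,
                 structures = catalog$groups[[group_id]],
                 spacing = as.numeric(spacing)),
            class = "group_label_map")
}

#' Combine per-group label maps into a composite segmentation
#'
#' The inverse of \code{\link{decode_group}}: each group's integer labels
#' become that group's binary masks; overlap across groups is preserved
#' verbatim because groups never share a mask.
#'
#' @param group_maps Named list with one \code{\link{group_label_map}} per
#'   catalog group.
#' @param catalog A \code{\link{structure_catalog}}.
#' @return A \code{\link{composite_segmentation}}.
#' @export
encode_composite <- function(group_maps, catalog = structure_catalog()) {
  if (!setequal(names(group_maps), names(catalog$groups)))
    stop("need one label map per group: ",
         paste(names(catalog$groups), collapse = ", "))
  dims <- dim(group_maps[[1]]$labels)
  spacing <- group_maps[[1]]$spacing
  masks <- list()
  for (g in names(catalog$groups)) {
    gm <- group_maps[[g]]
    if (!identical(dim(gm$labels), dims)) stop("mismatched grids (group ", g, ")")
    nm <- catalog$groups[[g]]
    for (k in seq_along(nm)) masks[[nm[k]]] <- gm$labels == k
  }
  composite_segmentation(masks, spacing, catalog)
}

#' Extract one group's integer label map from a composite
#'
#' @param composite A \code{\link{composite_segmentation}}.
#' @param group_id Group id.
#' @return A \code{\link{group_label_map}}; background 0, structures in
#'   catalog order. Within-group disjointness is a class invariant of the
#'   composite, so the encoding is exactly invertible.
#' @export
decode_group <- function(composite, group_id) {
  catalog <- composite$catalog
  if (!group_id %in% names(catalog$groups)) stop("unknown group: ", group_id)
  nm <- catalog$groups[[group_id]]
  labels <- array(0L, dim(composite$masks[[1]]))
  for (k in seq_along(nm)) {
    m <- composite$masks[[nm[k]]]
    if (any(labels[m] != 0L))
      stop("within-group overlap in group ", group_id)
    labels[m] <- k
  }
  group_label_map(labels, group_id, catalog, composite$spacing)
}

#' Write / read a composite segmentation
#'
#' On disk a composite is a 4-D NIfTI (x, y, z, structure) in fixed catalog
#' order plus a JSON sidecar (same path with extension
#' \code{.json}) naming the channels and groups — lossless under
#' cross-group overlap.
#'
#' @param composite A \code{\link{composite_segmentation}}.
#' @param path Output path (\code{.nii.gz}).
#' @return \code{path} (write) or the composite (read).
#' @export
write_composite <- function(composite, path) {
  nm <- catalog_structures(composite$catalog)
  dims <- dim(composite$masks[[1]])
  arr <- array(0L, c(dims, length(nm)))
  for (k in seq_along(nm)) arr[, , , k] <- composite$masks[[nm[k]]] + 0L
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(composite$spacing, 1)
  xf <- diag(4)
  diag(xf)[1:3] <- composite$spacing
  xf[1:3, 4] <- composite$origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  sidecar <- list(structures = nm, groups = composite$catalog$groups,
                  spacing = composite$spacing)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' @rdname write_composite
#' @param catalog Catalog the stored channels must match.
#' @export
read_composite <- function(path, catalog = structure_catalog()) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected 4-D composite NIfTI: ", path)
  sc <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  nm <- sc$structures
  if (!identical(nm, catalog_structures(catalog)))
    stop("sidecar channel order does not match catalog: ", path)
  hdr <- RNifti::niftiHeader(img)
  spacing <- as.numeric(hdr$pixdim[2:4])
  xf <- RNifti::xform(img)
  arr <- array(as.integer(img), d)
  masks <- setNames(lapply(seq_along(nm), function(k)
    array(arr[, , , k] != 0L, d[1:3])), nm)
  composite_segmentation(masks, spacing, catalog, origin = as.numeric(xf[1:3, 4]))
}
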