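# Evaluation metrics. Surfaces are border voxels (mask voxels 6-adjacent to
# background, volume edge counting as background); surface-to-surface
# nearest distances are exact Euclidean distances (mm) from the distance
# transform, matching an all-pairs brute-force oracle.

surface_points <- function(mask) which(border_voxels(mask))

surface_distances <- function(pred, ref, spacing) {
  sp <- border_voxels(pred)
  sr <- border_voxels(ref)
  dims <- dim(pred)
  d_to_ref <- array(cpp_edt(as.logical(sr), as.integer(dims),
                            as.numeric(spacing)), dims)
  d_to_pred <- array(cpp_edt(as.logical(sp), as.integer(dims),
                             as.numeric(spacing)), dims)
  list(ab = d_to_ref[sp], ba = d_to_pred[sr])
}

#' Dice similarity coefficient
#'
#' \code{2|A n B| / (|A| + |B|)}. Two empty masks agree degenerately
#' (DSC 1); one empty mask scores 0.
#'
#' @param pred,ref Logical arrays on one grid.
#' @return DSC in [0, 1].
#' @export
dsc <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) stop("grid mismatch")
  a <- sum(pred); b <- sum(ref)
  if (a + b == 0) return(1)
  2 * sum(pred & ref) / (a + b)
}

#' Surface Dice
#'
#' Fraction of the two masks' surfaces lying within a distance tolerance of
#' the opposing surface:
#' \code{(|S_pred within tol of S_ref| + |S_ref within tol of S_pred|) /
#' (|S_pred| + |S_ref|)}. The tolerance is given in voxels (default 2) and
#' converted to mm as \code{tolerance * mean(spacing)} on the working grid.
#'
#' @param pred,ref Logical arrays.
#' @param spacing Voxel spacing (mm).
#' @param tolerance Tolerance in voxels.
#' @param tolerance_mm Explicit tolerance in mm (overrides
#'   \code{tolerance}).
#' @return Surface Dice in [0, 1]; NA if exactly one mask is empty.
#' @export
surface_dice <- function(pred, ref, spacing = c(1, 1, 1), tolerance = 2,
                         tolerance_mm = NULL) {
  if (!identical(dim(pred), dim(ref))) stop("grid mismatch")
  if (!any(pred) && !any(ref)) return(1)
  if (!any(pred) || !any(ref)) return(NA_real_)
  tol <- tolerance_mm %||% (tolerance * mean(spacing))
  d <- surface_distances(pred, ref, spacing)
  (sum(d$ab <= tol + 1e-12) + sum(d$ba <= tol + 1e-12)) /
    (length(d$ab) + length(d$ba))
}

#' 95% Hausdorff distance (mm)
#'
#' Linear-interpolation (type-7) 95th percentile of the pooled symmetric
#' multiset of surface-to-surface nearest distances. Identical masks score
#' 0; an empty mask has no surface and the value is NA (the failure/discard
#' rule applies downstream).
#'
#' @param pred,ref Logical arrays.
#' @param spacing Voxel spacing (mm).
#' @param percentile Percentile in [0, 1].
#' @return Distance in mm, or NA on empty input.
#' @export
hd95 <- function(pred, ref, spacing = c(1, 1, 1), percentile = 0.95) {
  if (!identical(dim(pred), dim(ref))) stop("grid mismatch")
  if (!any(pred) && !any(ref)) return(0)
  if (!any(pred) || !any(ref)) return(NA_real_)
  d <- surface_distances(pred, ref, spacing)
  unname(quantile(c(d$ab, d$ba), percentile, type = 7))
}

#' Mean surface distance (mm)
#'
#' Mean of the pooled symmetric surface-to-surface nearest distances.
#'
#' @inheritParams hd95
#' @return Distance in mm, or NA on empty input.
#' @export
msd <- function(pred, ref, spacing = c(1, 1, 1)) {
  if (!identical(dim(pred), dim(ref))) stop("grid mismatch")
  if (!any(pred) && !any(ref)) return(0)
  if (!any(pred) || !any(ref)) return(NA_real_)
  d <- surface_distances(pred, ref, spacing)
  mean(c(d$ab, d$ba))
}

#' Skeletonize a 3-D mask
#'
#' Topology-preserving sequential thinning (26-connected foreground,
#' 6-connected background, curve endpoints preserved), producing a
#' one-voxel-wide centerline for tubular inputs. Deterministic.
#'
#' @param mask Logical 3-D array.
#' @return Logical array, a subset of \code{mask}.
#' @export
skeletonize_mask <- function(mask) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  array(cpp_thin(as.logical(mask), as.integer(dims)), dims)
}

#' Centerline Dice for tubular structures
#'
#' Topology precision is the fraction of the predicted skeleton inside the
#' reference mask; topology sensitivity the fraction of the reference
#' skeleton inside the prediction; clDice is their harmonic mean. Suited to
#' thin vessels, where small displacements crush the volumetric Dice.
#'
#' @param pred,ref Logical arrays on one grid.
#' @return clDice in [0, 1]; NA when either skeleton is empty (failure
#'   flag downstream); 1 when both masks are empty.
#' @export
centerline_dice <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) stop("grid mismatch")
  if (!any(pred) && !any(ref)) return(1)
  sp <- skeletonize_mask(pred)
  sr <- skeletonize_mask(ref)
  if (!any(sp) || !any(sr)) return(NA_real_)
  tprec <- sum(sp & ref) / sum(sp)
  tsens <- sum(sr & pred) / sum(sr)
  if (tprec + tsens == 0) return(0)
  2 * tprec * tsens / (tprec + tsens)
}

#' Evaluate one predicted composite against its reference
#'
#' DSC, surface Dice, HD95 and MSD for all 20 structures, plus clDice for
#' the coronary arteries (84 records per case). When a prediction (or
#' reference) is empty, its distance-based records carry
#' \code{failed = TRUE} and no finite value (infinite-distance discard
#' rule); its DSC is 0.
#'
#' @param pred,ref \code{composite_segmentation}s on one grid and catalog.
#' @param case Case identifier for the records.
#' @param sdice_tolerance Surface-Dice tolerance in voxels.
#' @return Data frame: case, structure, metric, value, failed.
#' @export
evaluate_case <- function(pred, ref, case = "case", sdice_tolerance = 2) {
  if (!identical(catalog_structures(pred$catalog),
                 catalog_structures(ref$catalog)))
    stop("catalog mismatch")
  if (!identical(dim(pred$masks[[1]]), dim(ref$masks[[1]])))
    stop("grid mismatch")
  spacing <- ref$spacing
  rows <- list()
  add <- function(structure, metric, value) {
    failed <- is.na(value)
    rows[[length(rows) + 1L]] <<- data.frame(
      case = case, structure = structure, metric = metric,
      value = if (failed) NA_real_ else value, failed = failed,
      stringsAsFactors = FALSE)
  }
  cas <- coronary_structures(ref$catalog)
  for (nm in catalog_structures(ref$catalog)) {
    p <- pred$masks[[nm]]; r <- ref$masks[[nm]]
    add(nm, "dsc", dsc(p, r))
    add(nm, "sdice", surface_dice(p, r, spacing, sdice_tolerance))
    add(nm, "hd95", hd95(p, r, spacing))
    add(nm, "msd", msd(p, r, spacing))
    if (nm %in% cas) add(nm, "cldice", centerline_dice(p, r))
  }
  do.call(rbind, rows)
}
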