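# Preprocessing: intensity windowing (CT-like only), cropping to the heart,
# resampling to the working isotropic grid, z-score normalisation.
# Physical convention: a volume's origin is the centre of its first voxel,
# so the grid corner sits at origin - spacing/2; resampling preserves the
# corner (half-voxel alignment), which keeps physical extents comparable
# across grids.

axis_index <- function(n_src, spacing_src, corner_off, n_dst, spacing_dst) {
  # continuous (1-based) source index of each destination voxel centre
  ((seq_len(n_dst) - 0.5) * spacing_dst + corner_off) / spacing_src + 0.5
}

#' Resample a volume to a new voxel spacing
#'
#' Grid-corner-aligned resampling: the output grid covers the same physical
#' extent (rounded to whole voxels) and samples the input at output voxel
#' centres, trilinearly for images or by nearest neighbour for label-like
#' data. Border samples are clamped.
#'
#' @param vol A \code{\link{as_volume}}.
#' @param new_spacing Target spacing (mm), length 1 or 3.
#' @param interp \code{"linear"} or \code{"nearest"}.
#' @return The resampled \code{volume}.
#' @export
resample_volume <- function(vol, new_spacing, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  nsp <- rep(as.numeric(new_spacing), length.out = 3)
  d <- dim(vol$data)
  nd <- pmax(1L, as.integer(round(d * vol$spacing / nsp)))
  u <- lapply(1:3, function(a) axis_index(d[a], vol$spacing[a], 0, nd[a], nsp[a]))
  data <- interp3(vol$data, u, interp)
  as_volume(data, nsp, vol$origin - vol$spacing / 2 + nsp / 2, vol$modality)
}

interp3 <- function(x, u, interp) {
  d <- dim(x)
  if (interp == "nearest") {
    idx <- lapply(1:3, function(a) pmin(pmax(round(u[[a]]), 1L), d[a]))
    return(x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  i0 <- lapply(1:3, function(a) pmin(pmax(floor(u[[a]]), 1L), d[a]))
  i1 <- lapply(1:3, function(a) pmin(i0[[a]] + 1L, d[a]))
  w <- lapply(1:3, function(a) pmin(pmax(u[[a]] - i0[[a]], 0), 1))
  nd <- vapply(u, length, integer(1))
  out <- array(0, nd)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    ix <- if (a == 0) i0[[1]] else i1[[1]]
    iy <- if (b == 0) i0[[2]] else i1[[2]]
    iz <- if (cc == 0) i0[[3]] else i1[[3]]
    wx <- if (a == 0) 1 - w[[1]] else w[[1]]
    wy <- if (b == 0) 1 - w[[2]] else w[[2]]
    wz <- if (cc == 0) 1 - w[[3]] else w[[3]]
    wt <- outer(outer(wx, wy, "*"), wz, "*")
    out <- out + wt * x[ix, iy, iz, drop = FALSE]
  }
  out
}

# nearest-neighbour lookup of a source array on an arbitrary destination
# grid, by physical position; destinations outside the source get `fill`
resample_to_grid <- function(src, src_spacing, src_origin, dst_dims,
                             dst_spacing, dst_origin, fill = 0L) {
  corner_src <- src_origin - src_spacing / 2
  corner_dst <- dst_origin - dst_spacing / 2
  d <- dim(src)
  u <- lapply(1:3, function(a)
    ((seq_len(dst_dims[a]) - 0.5) * dst_spacing[a] + corner_dst[a] -
       corner_src[a]) / src_spacing[a] + 0.5)
  idx <- lapply(u, round)
  valid <- lapply(1:3, function(a) idx[[a]] >= 1L & idx[[a]] <= d[a])
  cl <- lapply(1:3, function(a) pmin(pmax(idx[[a]], 1L), d[a]))
  out <- src[cl[[1]], cl[[2]], cl[[3]], drop = FALSE]
  bad <- !outer(outer(valid[[1]], valid[[2]], "&"), valid[[3]], "&")
  out[bad] <- fill
  out
}

#' Window and normalise a volume
#'
#' CT-like modalities are clipped to the HU window (default [-250, 550]);
#' MR-like intensities are left unwindowed. All modalities are then
#' resampled to the working spacing (default 1.5 mm isotropic, linear
#' interpolation) and z-score standardised to zero mean, unit variance. A
#' constant image cannot be scaled; it is centred only and a message is
#' emitted.
#'
#' @param vol A \code{\link{as_volume}}.
#' @param config A \code{\link{train_config}} (supplies window and target
#'   spacing).
#' @param resample Set FALSE to skip resampling (already on the grid).
#' @return The preprocessed \code{volume}.
#' @export
preprocess_volume <- function(vol, config = train_config(), resample = TRUE) {
  x <- vol$data
  if (ct_like(vol$modality)) {
    x[x < config$window[1]] <- config$window[1]
    x[x > config$window[2]] <- config$window[2]
    vol <- as_volume(x, vol$spacing, vol$origin, vol$modality)
  }
  if (resample && any(abs(vol$spacing - config$target_spacing) > 1e-9))
    vol <- resample_volume(vol, config$target_spacing, "linear")
  x <- vol$data
  s <- sd(x)
  if (s < 1e-12) {
    message("constant image: centring without scaling")
    x <- x - mean(x)
  } else {
    x <- (x - mean(x)) / s
  }
  as_volume(x, vol$spacing, vol$origin, vol$modality)
}

#' Crop a volume to the heart bounding box
#'
#' Tight bounding box of the whole-heart mask (or any foreground estimate)
#' dilated by a physical margin; the crop window is recorded so that
#' predictions can be mapped back onto the original grid with
#' \code{\link{uncrop_array}}.
#'
#' @param vol A \code{\link{as_volume}}.
#' @param mask Logical array on the same grid (e.g. the WH mask), or a
#'   \code{composite_segmentation} whose WH mask is used.
#' @param margin_mm Margin added on every side (mm).
#' @return List: \code{volume} (cropped) and \code{crop}
#'   (\code{lo}, \code{hi}, \code{orig_dims}).
#' @export
crop_to_heart <- function(vol, mask, margin_mm = 10) {
  if (inherits(mask, "composite_segmentation")) mask <- mask$masks$WH
  if (!any(mask)) stop("empty heart mask: nothing to crop to")
  if (!identical(dim(mask), dim(vol$data))) stop("mask grid mismatch")
  idx <- which(mask, arr.ind = TRUE)
  mg <- as.integer(round(margin_mm / vol$spacing))
  lo <- pmax(1L, apply(idx, 2, min) - mg)
  hi <- pmin(dim(vol$data), apply(idx, 2, max) + mg)
  crop <- list(lo = as.integer(lo), hi = as.integer(hi),
               orig_dims = dim(vol$data))
  v <- as_volume(vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
                 vol$spacing, vol$origin + (lo - 1L) * vol$spacing,
                 vol$modality)
  list(volume = v, crop = crop)
}

#' @rdname crop_to_heart
#' @param arr Array on the cropped grid (labels or predictions).
#' @param crop The recorded crop window.
#' @param fill Value for voxels outside the crop.
#' @return \code{uncrop_array}: the array restored onto the original grid.
#' @export
uncrop_array <- function(arr, crop, fill = 0L) {
  out <- array(fill, crop$orig_dims)
  out[crop$lo[1]:crop$hi[1], crop$lo[2]:crop$hi[2], crop$lo[3]:crop$hi[3]] <- arr
  out
}

#' @rdname crop_to_heart
#' @param composite A \code{composite_segmentation} to crop identically.
#' @return \code{crop_composite}: the cropped composite.
#' @export
crop_composite <- function(composite, crop) {
  masks <- lapply(composite$masks, function(m)
    m[crop$lo[1]:crop$hi[1], crop$lo[2]:crop$hi[2], crop$lo[3]:crop$hi[3],
      drop = FALSE])
  composite_segmentation(masks, composite$spacing, composite$catalog,
                         composite$origin + (crop$lo - 1L) * composite$spacing)
}

# full preprocessing of one labeled/unlabeled case: window -> crop (to the
# reference WH when labels exist, else to an intensity-foreground estimate)
# -> resample -> normalise; group label maps are looked up on the final
# image grid by physical position (nearest neighbour).
preprocess_case <- function(vol, composite = NULL, config = train_config()) {
  x <- vol$data
  if (ct_like(vol$modality)) {
    x[x < config$window[1]] <- config$window[1]
    x[x > config$window[2]] <- config$window[2]
    vol <- as_volume(x, vol$spacing, vol$origin, vol$modality)
  }
  if (config$crop_margin_mm >= 0) {
    wh <- if (!is.null(composite))
      resample_to_grid(composite$masks$WH + 0L, composite$spacing,
                       composite$origin, dim(vol$data), vol$spacing,
                       vol$origin) > 0L
    else vol$data > stats::quantile(vol$data, 0.75)
    if (any(wh))
      vol <- crop_to_heart(vol, wh, config$crop_margin_mm)$volume
  }
  vol <- preprocess_volume(vol, config, resample = TRUE)
  out <- list(image = vol)
  if (!is.null(composite)) {
    gm <- list()
    for (g in names(composite$catalog$groups)) {
      lab <- decode_group(composite, g)$labels
      gm[[g]] <- resample_to_grid(lab, composite$spacing, composite$origin,
                                  dim(vol$data), vol$spacing, vol$origin)
    }
    out$group_maps <- gm
    out$catalog <- composite$catalog
  }
  out
}
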